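ATF	1.0
2	3
"AcquisitionMode=Episodic Stimulation"
"SweepStartTimesMS=0,2.0"
"Time (ms)"	"Trace #1 (pA)"	"Trace #2 (pA)"
0.0	-20.289	-36.174
0.1	-21.194	-39.684
0.2	-21.89	-41.9
0.3	-22.984	-44.085
0.4	-23.102	-44.982
0.5	-23.558	-45.956
0.6	-23.859	-46.028
0.7	-23.796	-46.533
0.8	-24.689	-47.188
0.9	-24.093	-47.744
1.0	-24.813	-47.302
1.1	-25.02	-47.438
1.2	-24.966	-47.562
1.3	-24.73	-47.622
1.4	-24.803	-47.993
1.5	-24.975	-47.707
1.6	-25.194	-47.552
1.7	-25.123	-47.947
1.8	-24.577	-48.264
1.9	-24.897	-47.741
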