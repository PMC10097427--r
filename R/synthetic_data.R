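# run expr under a local RNG stream without disturbing the caller's state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Beta distribution of the attached-membrane fraction, fitted so that the
# quartiles match the measured median 27.36 % and IQR 24.7-30.0 %
# (least-squares on the three quantiles; residual < 6e-4 per quantile)
.attached_fraction_beta <- c(shape1 = 35.3770, shape2 = 93.5730)

#' Photostimulus waveform
#'
#' Biphasic, charge-balanced, cathodic-leading stimulus delivered to the
#' cleft node.  Two representations are supported:
#'
#' * `mode = "current"` (default): injected photocurrent.  During the light
#'   pulse the current charges exponentially (time constant `tau_on`) toward
#'   the cathodic plateau `-amplitude`; at light-off an anodic discharge
#'   releases exactly the accumulated charge with time constant `tau_off`,
#'   so the waveform is charge-balanced by construction.
#' * `mode = "voltage"`: prescribed source voltage behind the electrode
#'   capacitance `C_E`, charging toward `-amplitude` during the pulse and
#'   relaxing back to zero afterwards (purely capacitive coupling).
#'
#' The peak amplitude is a saturating function of light intensity,
#' `amplitude = amp_max * intensity / (intensity + intensity_half)`; the
#' calibration constants are explicit configuration values, chosen so the
#' default two-domain cell sees attached-membrane deflections of a few tens
#' of millivolts at the strongest intensity used in the study (13 mW mm^-2).
#'
#' @param intensity light intensity (mW mm^-2); 0 yields the zero waveform
#' @param onset light-on time (s)
#' @param duration pulse duration (s)
#' @param mode `"current"` or `"voltage"`
#' @param tau_on,tau_off charging/discharging time constants (s).  In
#'   current mode the discharge returns the full accumulated charge, so its
#'   peak is `Q_on/tau_off`; the default `tau_off` of 2 ms keeps the
#'   off-transient a small multiple of the plateau, as observed for these
#'   devices
#' @param amp_max saturation amplitude (A for current mode, V for voltage
#'   mode)
#' @param intensity_half half-saturation intensity (mW mm^-2)
#' @return object of class `photostimulus`; fields include the resolved
#'   `amplitude`
#' @export
photostimulus <- function(intensity = 13, onset = 0.020, duration = 0.005,
                          mode = c("current", "voltage"),
                          tau_on = 5e-4,
                          tau_off = if (mode[1] == "current") 2e-3 else 5e-4,
                          amp_max = if (mode[1] == "current") 4.5e-9 else 0.45,
                          intensity_half = 4) {
  mode <- match.arg(mode)
  stopifnot(intensity >= 0, duration > 0, tau_on > 0, tau_off > 0)
  amplitude <- amp_max * intensity / (intensity + intensity_half)
  structure(list(intensity = intensity, onset = onset, duration = duration,
                 mode = mode, tau_on = tau_on, tau_off = tau_off,
                 amplitude = amplitude, amp_max = amp_max,
                 intensity_half = intensity_half),
            class = "photostimulus")
}

#' @rdname photostimulus
#' @param stim a [photostimulus()]
#' @param t evaluation times (s)
#' @details `stimulus_waveform()` evaluates the waveform and its time
#'   derivative on a time grid (closed forms, no numerical differentiation).
#' @export
stimulus_waveform <- function(stim, t) {
  list(value = stimulus_value_at(stim, t),
       deriv = stimulus_deriv_at(stim, t))
}

stimulus_value_at <- function(stim, t) {
  a <- stim$amplitude
  on <- stim$onset; off <- stim$onset + stim$duration
  v <- numeric(length(t))
  if (a == 0) return(v)
  inp <- t >= on & t < off
  post <- t >= off
  v[inp] <- -a * (1 - exp(-(t[inp] - on) / stim$tau_on))
  if (stim$mode == "current") {
    # anodic discharge carrying exactly the cathodic charge
    q_on <- a * (stim$duration - stim$tau_on * (1 - exp(-stim$duration / stim$tau_on)))
    v[post] <- (q_on / stim$tau_off) * exp(-(t[post] - off) / stim$tau_off)
  } else {
    v_off <- -a * (1 - exp(-stim$duration / stim$tau_on))
    v[post] <- v_off * exp(-(t[post] - off) / stim$tau_off)
  }
  v
}

stimulus_deriv_at <- function(stim, t) {
  a <- stim$amplitude
  on <- stim$onset; off <- stim$onset + stim$duration
  d <- numeric(length(t))
  if (a == 0) return(d)
  inp <- t >= on & t < off
  post <- t >= off
  d[inp] <- -(a / stim$tau_on) * exp(-(t[inp] - on) / stim$tau_on)
  if (stim$mode == "current") {
    q_on <- a * (stim$duration - stim$tau_on * (1 - exp(-stim$duration / stim$tau_on)))
    d[post] <- -(q_on / stim$tau_off^2) * exp(-(t[post] - off) / stim$tau_off)
  } else {
    v_off <- -a * (1 - exp(-stim$duration / stim$tau_on))
    d[post] <- -(v_off / stim$tau_off) * exp(-(t[post] - off) / stim$tau_off)
  }
  d
}

#' Draw a synthetic cell
#'
#' Draws one whole-cell recording's worth of latent parameters: the attached
#' membrane fraction from the Beta distribution matched to the measured
#' median (27.36 %) and interquartile range (24.7-30.0 %), and circuit
#' parameters from log-uniform ranges typical of HEK293 whole-cell
#' recordings (C_M 12-25 pF, R_S 4-15 MOhm, R_seal 2-10 GOhm,
#' R_B 0.5-2 GOhm, N 8000-20000 channels).  Fully reproducible from the
#' seed, which is recorded in the result.
#'
#' @param seed integer seed
#' @return object of class `cell_spec` with fields `patch`
#'   ([patch_params()]), `channels` ([channel_population()]), `geom`
#'   ([two_domain_geometry()]) and `seed`
#' @export
generate_cell <- function(seed) {
  with_seed(seed, {
    fraction <- rbeta(1, .attached_fraction_beta[1], .attached_fraction_beta[2])
    lunif <- function(lo, hi) exp(runif(1, log(lo), log(hi)))
    C_M <- lunif(12e-12, 25e-12)
    patch <- patch_params(C_M = C_M,
                          R_S = lunif(4e6, 15e6),
                          R_seal = lunif(2e9, 10e9),
                          R_B = lunif(0.5e9, 2e9))
    channels <- channel_population(N = lunif(8000, 20000))
    geom <- two_domain_geometry(A_M = C_M / 0.01, fraction = fraction)
    structure(list(patch = patch, channels = channels, geom = geom,
                   seed = seed),
              class = "cell_spec")
  })
}

#' Generate synthetic whole-cell sweeps
#'
#' Forward-simulates the chosen model for every sweep of a protocol family,
#' adds white Gaussian current noise scaled to the peak absolute unfiltered
#' current, and applies the recording filter.  The noise-free latent
#' trajectories are stored alongside each sweep for recovery tests.
#'
#' @param cell a [generate_cell()] result (or a compatible list with
#'   `patch`, `channels`, `geom`)
#' @param protocol_family list of per-sweep protocols from [step_family()]
#'   or `hek_activation_protocol()$voltage`
#' @param light a [light_protocol()] or NULL
#' @param rates a [rate_params()]
#' @param noise_rms noise amplitude as a fraction of the peak |I| (default
#'   0.02); 0 gives the raw simulation
#' @param fs sampling rate (Hz)
#' @param seed integer seed for the noise stream
#' @param model `"single"` (whole-cell circuit) or `"two_domain"`
#' @param stimulus a [photostimulus()] template for `model = "two_domain"`;
#'   its onset/duration are taken from `light` when given
#' @param cleft a [cleft_params()] for the two-domain model
#' @param filter a [filter_spec()] or NULL
#' @param h_max maximum integrator substep (s), threaded to the simulators
#' @param hold_s optional override of each protocol's holding duration
#'   (sweeps start from the holding steady state, so a shortened hold is
#'   dynamically equivalent and much cheaper)
#' @return list of [new_sweep()] objects (class `sweep_set`); each carries
#'   attributes `i_truth` (noise-free filtered current), `i_raw`
#'   (noise-free unfiltered), `p_open`, `v_m`
#' @export
generate_sweeps <- function(cell, protocol_family, light = NULL,
                            rates = kv13_rates(), noise_rms = 0.02,
                            fs = 25000, seed = 1, model = c("single", "two_domain"),
                            stimulus = NULL, cleft = cleft_params(),
                            filter = filter_spec(), h_max = 2e-5,
                            hold_s = NULL) {
  model <- match.arg(model)
  with_seed(seed, {
    sweeps <- lapply(protocol_family, function(vp) {
      if (!is.null(hold_s)) {
        shift <- vp$durations[1] - hold_s
        vp$durations[1] <- hold_s
      } else shift <- 0
      lp <- light
      if (!is.null(lp) && length(lp$onset)) lp$onset <- lp$onset - shift
      prot <- sample_protocol(vp, lp, fs)
      if (model == "single") {
        sw <- simulate_voltage_clamp(prot, cell$patch, cell$channels, rates,
                                     filter = NULL, h_max = h_max,
                                     step_level = vp$step_level %||% NA_real_)
      } else {
        stim <- stimulus
        if (!is.null(stim) && !is.null(lp) && length(lp$onset)) {
          stim$onset <- lp$onset[1]
          stim$duration <- lp$duration[1]
        }
        sw <- simulate_two_domain("vc", prot, cell$patch, cell$geom, cleft,
                                  cell$channels, rates, stimulus = stim,
                                  filter = NULL, h_max = h_max,
                                  step_level = vp$step_level %||% NA_real_)$sweep
      }
      i_raw <- attr(sw, "i_raw")
      i_truth <- if (is.null(filter)) i_raw
                 else apply_filter(i_raw, fs, filter)
      i_noisy <- i_raw
      if (noise_rms > 0)
        i_noisy <- i_raw + rnorm(length(i_raw), 0, noise_rms * max(abs(i_raw)))
      sw$i_out <- if (is.null(filter)) i_noisy
                  else apply_filter(i_noisy, fs, filter)
      attr(sw, "i_truth") <- i_truth
      attr(sw, "cell_seed") <- cell$seed
      sw
    })
    class(sweeps) <- c("sweep_set", "list")
    sweeps
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
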