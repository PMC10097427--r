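#' Whole-cell patch parameters
#'
#' Elements of the whole-cell equivalent circuit: total membrane capacitance
#' `C_M`, series (access) resistance `R_S`, pipette seal resistance `R_seal`,
#' background membrane resistance `R_B` (conductance `G_B = 1/R_B`) and the
#' background reversal potential `E_VHEK`.  Series-resistance compensation is
#' deliberately absent: the access resistance is part of the model, matching
#' uncompensated recordings.
#'
#' @param C_M total membrane capacitance (F)
#' @param R_S series resistance (Ohm)
#' @param R_seal seal resistance (Ohm)
#' @param R_B background membrane resistance (Ohm)
#' @param E_VHEK background (leak) reversal potential (V); untransfected
#'   HEK293 cells rest near -40 mV
#' @return object of class `patch_params`
#' @export
patch_params <- function(C_M = 20e-12, R_S = 8e6, R_seal = 4e9, R_B = 1e9,
                         E_VHEK = -0.040) {
  if (any(c(C_M, R_S, R_seal, R_B) <= 0))
    stop("C_M, R_S, R_seal and R_B must all be > 0")
  structure(list(C_M = C_M, R_S = R_S, R_seal = R_seal, R_B = R_B,
                 E_VHEK = E_VHEK),
            class = "patch_params")
}

#' Recording filter specification
#'
#' The acquisition chain is modelled as a causal low-pass Bessel filter
#' applied to the output current.  The default is the 4th-order filter with a
#' 2 kHz cutoff (-3 dB) discretised by impulse invariance.
#'
#' @param order filter order
#' @param cutoff -3 dB cutoff frequency (Hz)
#' @param discretization discretisation method tag (only
#'   `"impulse_invariance"` is implemented)
#' @return object of class `filter_spec`
#' @export
filter_spec <- function(order = 4L, cutoff = 2000,
                        discretization = "impulse_invariance") {
  stopifnot(order >= 1, cutoff > 0,
            discretization == "impulse_invariance")
  structure(list(order = as.integer(order), cutoff = cutoff,
                 discretization = discretization),
            class = "filter_spec")
}

# Analog Bessel low-pass prototype: poles of the reverse Bessel polynomial
# theta_n(s), rescaled so the -3 dB point sits at the requested cutoff.
# Returns poles (rad/s) and the DC-unity gain constant.
bessel_analog <- function(order, cutoff) {
  k <- 0:order
  # coefficients of theta_n(s), ascending in s
  coefs <- factorial(2 * order - k) /
    (2^(order - k) * factorial(k) * factorial(order - k))
  poles <- polyroot(coefs)
  magsq <- function(w) {
    b <- abs(vapply(w, function(wi)
      sum(coefs * (1i * wi)^k), complex(1)))^2
    coefs[1]^2 / b
  }
  w3 <- uniroot(function(w) magsq(w) - 0.5, c(1e-6, 10 * order),
                tol = 1e-14)$root
  w0 <- 2 * pi * cutoff
  poles <- poles * (w0 / w3)
  gain <- Re(prod(-poles))
  list(poles = poles, gain = gain)
}

# Impulse-invariance discretisation of the analog prototype: partial
# fractions H(s) = sum r_i/(s - p_i), then
# H(z) = T * sum r_i / (1 - exp(p_i T) z^-1), recombined into real (b, a).
.filter_cache <- new.env(parent = emptyenv())

polymul <- function(x, y) {
  out <- rep(0 + 0i, length(x) + length(y) - 1L)
  for (i in seq_along(x))
    out[i + seq_along(y) - 1L] <- out[i + seq_along(y) - 1L] + x[i] * y
  out
}

bessel_digital <- function(spec, fs) {
  key <- paste(spec$order, spec$cutoff, fs, sep = "|")
  hit <- .filter_cache[[key]]
  if (!is.null(hit)) return(hit)
  proto <- bessel_analog(spec$order, spec$cutoff)
  p <- proto$poles
  nn <- length(p)
  r <- vapply(seq_len(nn), function(i)
    proto$gain / prod(p[i] - p[-i]), complex(1))
  T <- 1 / fs
  zp <- exp(p * T)
  a <- c(1 + 0i)
  for (i in seq_len(nn)) a <- polymul(a, c(1, -zp[i]))
  b <- rep(0 + 0i, nn)
  for (i in seq_len(nn)) {
    num <- c(1 + 0i)
    for (j in seq_len(nn)[-i]) num <- polymul(num, c(1, -zp[j]))
    b[seq_along(num)] <- b[seq_along(num)] + T * r[i] * num
  }
  b <- Re(b); a <- Re(a)
  # impulse invariance aliases a little DC gain away; rescale to exact unity
  b <- b * sum(a) / sum(b)
  .filter_cache[[key]] <- list(b = b, a = a)
  .filter_cache[[key]]
}

#' Apply the recording filter to a sampled signal
#'
#' Causal application of the impulse-invariance-discretised Bessel low-pass.
#' The DC gain of the discrete filter is within 1e-3 of unity for sampling
#' rates comfortably above the Nyquist bound enforced here.
#'
#' @param x signal (numeric vector)
#' @param fs sampling rate (Hz); must exceed `2 * cutoff`
#' @param spec a [filter_spec()]
#' @return filtered signal, same length as `x`
#' @export
apply_filter <- function(x, fs, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  if (fs <= 2 * spec$cutoff)
    stop("sampling rate must exceed twice the filter cutoff (fs = ", fs,
         " Hz, cutoff = ", spec$cutoff, " Hz)")
  ba <- bessel_digital(spec, fs)
  as.numeric(signal::filter(ba$b, ba$a, x))
}

#' Sweep container
#'
#' One aligned time series of command voltage, light intensity and measured
#' (or simulated) output: current `i_out` in voltage clamp, membrane voltage
#' `v_i` in current clamp.  Simulated sweeps additionally carry the latent
#' trajectories (unfiltered current, membrane voltage, open probabilities) as
#' attributes.
#'
#' @param t uniform, strictly increasing time grid (s)
#' @param v_cmd command voltage (V)
#' @param light light intensity trace (mW mm^-2)
#' @param i_out output current (A), voltage clamp
#' @param v_i measured voltage (V), current clamp
#' @param mode `"vc"` or `"cc"`
#' @param cell_id cell identifier
#' @param step_level step voltage of this sweep (V), if part of a family
#' @return data.frame of class `sweep` with metadata attributes
#' @export
new_sweep <- function(t, v_cmd, light, i_out = NULL, v_i = NULL,
                      mode = c("vc", "cc"), cell_id = NA_character_,
                      step_level = NA_real_) {
  mode <- match.arg(mode)
  n <- length(t)
  stopifnot(length(v_cmd) == n, length(light) == n)
  dt <- diff(t)
  if (n > 1 && (any(dt <= 0) || diff(range(dt)) > 1e-9 * max(dt)))
    stop("sweep time grid must be uniform and strictly increasing")
  df <- data.frame(t = t, v_cmd = v_cmd, light = light)
  if (!is.null(i_out)) { stopifnot(length(i_out) == n); df$i_out <- i_out }
  if (!is.null(v_i))   { stopifnot(length(v_i) == n);   df$v_i <- v_i }
  structure(df, class = c("sweep", "data.frame"),
            mode = mode, cell_id = cell_id, step_level = step_level,
            fs = if (n > 1) 1 / dt[1] else NA_real_)
}

solver_substeps <- function(dt, h_max = 2e-5) max(1L, ceiling(dt / h_max))

#' Simulate a voltage-clamp sweep of the whole-cell circuit
#'
#' Integrates the coupled membrane/gating system
#' `C_M dV/dt = (V_C - V)/R_S - G_B (V - E_VHEK) - I_Kv1.3(t, V)` with the
#' pipette node held at the command voltage through `R_S` (ideal amplifier),
#' and returns the measured current
#' `I_out = (V_C - V)/R_S + V_C/R_seal`, Bessel-filtered.  Cell and patch
#' parameters are constant over a sweep.
#'
#' @param protocol data.frame with columns `t`, `v_cmd` (and optionally
#'   `light`, carried through to the sweep), e.g. from [sample_protocol()]
#' @param patch a [patch_params()]
#' @param channels a [channel_population()], or NULL to disable channels
#' @param rates a [rate_params()] (4 closed states; required when channels
#'   are enabled)
#' @param filter a [filter_spec()], or NULL for unfiltered output
#' @param p0 initial gating state; default steady state at the first command
#'   voltage
#' @param V0 initial membrane voltage; default passive equilibrium at the
#'   first command voltage
#' @param h_max maximum integrator substep (s)
#' @param cell_id,step_level sweep metadata
#' @return a [new_sweep()] in `"vc"` mode; attributes `i_raw` (unfiltered
#'   current), `v_m` (membrane voltage) and `p_open` hold the latent
#'   trajectories
#' @export
simulate_voltage_clamp <- function(protocol, patch, channels = NULL,
                                   rates = NULL, filter = filter_spec(),
                                   p0 = NULL, V0 = NULL, h_max = 2e-5,
                                   cell_id = NA_character_,
                                   step_level = NA_real_) {
  stopifnot(inherits(patch, "patch_params"))
  t <- protocol$t
  vc <- protocol$v_cmd
  li <- if (!is.null(protocol$light)) protocol$light else rep(0, length(t))
  GB <- 1 / patch$R_B
  Ng <- 0; EK <- 0
  if (!is.null(channels)) {
    stopifnot(inherits(channels, "channel_population"),
              inherits(rates, "rate_params"))
    if (rates$n_closed != 4L)
      stop("the compiled integrator supports the 4-closed-state chain; use propagate() for other topologies")
    Ng <- channels$N * channels$g
    EK <- channels$E_K
  }
  if (is.null(V0)) {
    V0 <- passive_equilibrium(vc[1], patch)
    if (Ng > 0) V0 <- clamp_equilibrium(vc[1], patch, channels, rates)
  }
  if (is.null(p0)) {
    p0 <- if (Ng > 0) steady_state(V0, rates) else rep(1 / 5, 5)
  }
  rl <- if (!is.null(rates)) as_rate_list(rates)
        else as_rate_list(kv13_rates())
  dt <- t[2] - t[1]
  res <- cpp_simulate_single(t, vc, 0L, rl, Ng, EK, patch$C_M, patch$R_S,
                             patch$R_seal, GB, patch$E_VHEK, p0, V0,
                             solver_substeps(dt, h_max))
  res$I_out <- as.vector(res$I_out); res$V <- as.vector(res$V)
  if (any(!is.finite(res$I_out)))
    stop("voltage-clamp integration produced non-finite output (step ",
         which(!is.finite(res$I_out))[1], ")")
  i_f <- if (is.null(filter)) res$I_out
         else apply_filter(res$I_out, 1 / dt, filter)
  sw <- new_sweep(t, vc, li, i_out = i_f, mode = "vc", cell_id = cell_id,
                  step_level = step_level)
  attr(sw, "i_raw") <- res$I_out
  attr(sw, "v_m") <- res$V
  attr(sw, "p_open") <- res$p[, 5]
  attr(sw, "p_gating") <- res$p
  sw
}

#' Simulate a current-clamp sweep (I = 0 or injected current)
#'
#' The amplifier is an ideal voltage follower: the pipette carries only the
#' injected current `I_inj` (zero in I = 0 mode) and the seal leak is
#' neglected, so `C_M dV/dt = I_inj - G_B (V - E_VHEK) - I_Kv1.3`.
#'
#' @param I_inj injected current trace (A), one value per sample (scalars are
#'   recycled)
#' @param t time grid (s)
#' @inheritParams simulate_voltage_clamp
#' @return a [new_sweep()] in `"cc"` mode carrying `v_i`
#' @export
simulate_current_clamp <- function(t, I_inj = 0, patch, channels = NULL,
                                   rates = NULL, filter = NULL,
                                   p0 = NULL, V0 = NULL, h_max = 2e-5,
                                   cell_id = NA_character_) {
  stopifnot(inherits(patch, "patch_params"))
  ii <- rep_len(I_inj, length(t))
  GB <- 1 / patch$R_B
  Ng <- 0; EK <- 0
  if (!is.null(channels)) {
    stopifnot(inherits(channels, "channel_population"),
              inherits(rates, "rate_params"))
    Ng <- channels$N * channels$g
    EK <- channels$E_K
  }
  if (is.null(V0)) V0 <- patch$E_VHEK
  if (is.null(p0)) p0 <- if (Ng > 0) steady_state(V0, rates) else rep(1 / 5, 5)
  rl <- if (!is.null(rates)) as_rate_list(rates) else as_rate_list(kv13_rates())
  dt <- t[2] - t[1]
  res <- cpp_simulate_single(t, ii, 1L, rl, Ng, EK, patch$C_M, patch$R_S,
                             patch$R_seal, GB, patch$E_VHEK, p0, V0,
                             solver_substeps(dt, h_max))
  res$V <- as.vector(res$V)
  v <- if (is.null(filter)) res$V else apply_filter(res$V, 1 / dt, filter)
  sw <- new_sweep(t, rep(NA_real_, length(t)), rep(0, length(t)),
                  v_i = v, mode = "cc", cell_id = cell_id)
  attr(sw, "v_m") <- res$V
  attr(sw, "p_open") <- res$p[, 5]
  sw
}

# passive equilibrium of the clamped circuit (no channels)
passive_equilibrium <- function(vc, patch) {
  GB <- 1 / patch$R_B
  (vc / patch$R_S + GB * patch$E_VHEK) / (1 / patch$R_S + GB)
}

# self-consistent holding equilibrium with channels at steady state
clamp_equilibrium <- function(vc, patch, channels, rates) {
  GB <- 1 / patch$R_B
  Ng <- channels$N * channels$g
  f <- function(V) {
    pO <- steady_state(V, rates)[rates$n_closed + 1L]
    (vc - V) / patch$R_S - GB * (V - patch$E_VHEK) - Ng * pO * (V - channels$E_K)
  }
  lo <- min(vc, channels$E_K, patch$E_VHEK) - 0.05
  hi <- max(vc, channels$E_K, patch$E_VHEK) + 0.05
  uniroot(f, c(lo, hi), tol = 1e-12)$root
}

# steady-state output current at one command voltage (used by the per-cell
# channel-count fit)
steady_state_current <- function(vc, patch, channels, rates) {
  V <- clamp_equilibrium(vc, patch, channels, rates)
  (vc - V) / patch$R_S + vc / patch$R_seal
}

#' Adaptive-ODE reference simulation of the voltage-clamp circuit
#'
#' Same model as [simulate_voltage_clamp()] integrated by `deSolve::lsoda`
#' with tight tolerances; the independent cross-check path for the compiled
#' fixed-step scheme.
#'
#' @inheritParams simulate_voltage_clamp
#' @param rtol,atol integration tolerances
#' @return list with `t`, `V`, `p` (gating matrix) and unfiltered `I_out`
#' @export
simulate_voltage_clamp_ode <- function(protocol, patch, channels = NULL,
                                       rates = NULL, p0 = NULL, V0 = NULL,
                                       rtol = 1e-8, atol = 1e-12) {
  t <- protocol$t
  vcf <- approxfun(t, protocol$v_cmd, method = "constant", rule = 2)
  GB <- 1 / patch$R_B
  Ng <- if (!is.null(channels)) channels$N * channels$g else 0
  EK <- if (!is.null(channels)) channels$E_K else 0
  if (is.null(V0)) V0 <- passive_equilibrium(protocol$v_cmd[1], patch)
  if (is.null(p0)) p0 <- if (Ng > 0) steady_state(V0, rates) else rep(0.2, 5)
  y0 <- c(V = V0, p = p0)
  rhs <- function(tt, y, parms) {
    V <- y[1]; p <- y[-1]
    dp <- if (Ng > 0) as.vector(p %*% rate_matrix(V, rates)) else rep(0, 5)
    G <- Ng * p[5]
    dV <- ((vcf(tt) - V) / patch$R_S - GB * (V - patch$E_VHEK) -
             G * (V - EK)) / patch$C_M
    list(c(dV, dp))
  }
  sol <- deSolve::lsoda(y0, t, rhs, parms = NULL, rtol = rtol, atol = atol,
                        maxsteps = 50000)
  V <- sol[, 2]
  list(t = t, V = V, p = unname(sol[, -(1:2), drop = FALSE]),
       I_out = (vcf(t) - V) / patch$R_S + vcf(t) / patch$R_seal)
}
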