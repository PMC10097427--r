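#' Conductance-voltage curve from a sweep family
#'
#' For each step level V the chord conductance is
#' `G(V) = mean(I_out over window) / (V - E_rev)`, using the measured
#' reversal potential (default -73 mV).  Steps within 5 mV of the reversal
#' potential are excluded (driving force too small).  In a light condition
#' the window is typically placed in the late phase of the light pulse; in
#' the dark condition in the late phase of the step.
#'
#' @param sweeps a list of voltage-clamp [new_sweep()]s with `step_level`
#'   attributes (a `sweep_set`)
#' @param E_rev reversal potential (V)
#' @param window `c(t_start, t_end)` (s, sweep time) over which the current
#'   is averaged; must lie within the step segment
#' @param leak optional leak correction: `"none"` (default) or `"linear"`,
#'   which fits `I = G_leak*(V - E_leak)` to the window currents of steps at
#'   or below `leak_below` and subtracts it
#' @param leak_below most positive step (V) used for the linear leak fit
#' @return object of class `gv_curve`: data.frame with columns `V`, `G`,
#'   `G_norm`
#' @export
conductance_from_sweeps <- function(sweeps, E_rev = -0.073, window,
                                    leak = c("none", "linear"),
                                    leak_below = -0.080) {
  leak <- match.arg(leak)
  stopifnot(length(window) == 2, window[2] > window[1])
  lev <- vapply(sweeps, function(s) attr(s, "step_level"), numeric(1))
  if (any(is.na(lev))) stop("all sweeps need a step_level attribute")
  imean <- vapply(sweeps, function(s) {
    idx <- s$t >= window[1] & s$t <= window[2]
    if (!any(idx)) stop("averaging window contains no samples")
    # window must fall inside the final (step) segment
    if (any(s$v_cmd[idx] != attr(s, "step_level")))
      stop("averaging window lies outside the voltage step")
    mean(s$i_out[idx])
  }, numeric(1))
  if (leak == "linear") {
    sel <- lev <= leak_below + 1e-12
    if (sum(sel) < 2) stop("need at least two steps at or below leak_below for the leak fit")
    fit <- lm(imean[sel] ~ lev[sel])
    imean <- imean - (coef(fit)[1] + coef(fit)[2] * lev)
  }
  keep <- abs(lev - E_rev) > 0.005
  G <- imean[keep] / (lev[keep] - E_rev)
  ord <- order(lev[keep])
  out <- data.frame(V = lev[keep][ord], G = G[ord])
  out$G_norm <- if (max(abs(out$G)) > 0) out$G / max(out$G) else out$G
  structure(out, class = c("gv_curve", "data.frame"), E_rev = E_rev,
            window = window)
}

#' Boltzmann fit of a G-V curve
#'
#' Least-squares fit of `G(V) = G_max / (1 + exp(-(V - V50)/k))`.
#' Initialisation: `G_max = max(G)`, `V50` at half maximum by linear
#' interpolation, `k = 10 mV`.  A curve whose conductance spread is
#' negligible relative to its level is flagged degenerate and refused.
#'
#' @param curve a [conductance_from_sweeps()] result (or data.frame with
#'   columns `V`, `G`)
#' @return list with `G_max` (S), `V50` (V), `slope` (V, > 0) and the fit
#'   object
#' @export
boltzmann_fit <- function(curve) {
  V <- curve$V; G <- curve$G
  if (length(V) < 4) stop("need at least 4 points for a Boltzmann fit")
  if (diff(range(G)) <= 1e-6 * max(abs(G), 1e-30))
    stop("degenerate G-V curve: conductance is constant across voltage")
  start <- list(G_max = max(G),
                V50 = half_activation_interp(curve),
                k = 0.010)
  fit <- tryCatch(
    minpack.lm::nlsLM(G ~ G_max / (1 + exp(-(V - V50) / k)),
                      start = start, data = data.frame(V = V, G = G),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("Boltzmann fit did not converge: ",
                             conditionMessage(e), "; residual range ",
                             paste(signif(range(G), 4), collapse = " .. ")))
  cf <- coef(fit)
  if (cf[["k"]] <= 0) stop("Boltzmann fit returned non-positive slope")
  list(G_max = cf[["G_max"]], V50 = cf[["V50"]], slope = cf[["k"]], fit = fit)
}

#' Half-activation voltage by linear interpolation
#'
#' Interpolation-based readout of the voltage at half-maximal conductance,
#' the model-free alternative to [boltzmann_fit()].
#'
#' @param curve data.frame with columns `V` and `G`
#' @return voltage (V) where G crosses `max(G)/2`
#' @export
half_activation_interp <- function(curve) {
  V <- curve$V; G <- curve$G
  o <- order(V); V <- V[o]; G <- G[o]
  gh <- max(G) / 2
  above <- which(G >= gh)
  if (!length(above) || above[1] == 1) return(V[1])
  i <- above[1]
  V[i - 1] + (gh - G[i - 1]) * (V[i] - V[i - 1]) / (G[i] - G[i - 1])
}

#' Light-induced shift of the half-activation voltage
#'
#' `Delta G50 = V50(dark) - V50(light)`; positive when light shifts the
#' activation curve to more negative voltages (left shift).
#'
#' @param light_curve,dark_curve [conductance_from_sweeps()] results
#' @param method `"boltzmann"` (default) or `"interp"`
#' @return shift (V)
#' @export
g50_shift <- function(light_curve, dark_curve,
                      method = c("boltzmann", "interp")) {
  method <- match.arg(method)
  v50 <- function(cv) {
    if (method == "boltzmann") boltzmann_fit(cv)$V50
    else half_activation_interp(cv)
  }
  v50(dark_curve) - v50(light_curve)
}
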