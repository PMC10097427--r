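#' Two-domain membrane geometry
#'
#' The membrane of a cell adhering to the photocapacitor surface is split
#' into the attached domain (area `A_J`, facing the thin electrolyte cleft)
#' and the free domain (area `A_MJ = A_M - A_J`, facing the bath).  The
#' attached fraction measured by confocal reconstruction has median 27.36 %
#' (interquartile range 24.7-30.0 %), which is the default.
#'
#' @param A_M total membrane area (m^2); the default derives a nominal area
#'   from a 20 pF cell at 1 uF/cm^2 specific capacitance
#' @param fraction attached fraction `A_J / A_M`, in (0, 1)
#' @return object of class `two_domain_geometry` with fields `A_M`, `A_J`,
#'   `A_MJ`, `fraction`
#' @export
two_domain_geometry <- function(A_M = 2e-9, fraction = 0.2736) {
  if (!(fraction > 0 && fraction < 1)) stop("attached fraction must be in (0, 1)")
  if (A_M <= 0) stop("total membrane area must be > 0")
  structure(list(A_M = A_M, A_J = fraction * A_M,
                 A_MJ = (1 - fraction) * A_M, fraction = fraction),
            class = "two_domain_geometry")
}

#' Cleft coupling parameters
#'
#' `R_J` is the seal resistance between the sub-cell cleft and the bath;
#' `C_E` the interfacial capacitance of the photocapacitor electrode under
#' the attached membrane.  Neither is printed in the study; the defaults
#' (R_J = 10 MOhm, C_E scaled at 1 uF/cm^2 of attached area) are typical of
#' cell-substrate two-domain modelling and are reported in all outputs.
#'
#' @param R_J cleft seal resistance (Ohm)
#' @param C_E electrode interfacial capacitance (F); `NA` scales
#'   1 uF/cm^2 by the attached area at simulation time
#' @return object of class `cleft_params`
#' @export
cleft_params <- function(R_J = 10e6, C_E = NA_real_) {
  if (R_J <= 0) stop("R_J must be > 0")
  if (!is.na(C_E) && C_E <= 0) stop("C_E must be > 0")
  structure(list(R_J = R_J, C_E = C_E), class = "cleft_params")
}

resolve_CE <- function(cleft, geom) {
  if (!is.na(cleft$C_E)) cleft$C_E else 0.01 * geom$A_J  # 1 uF/cm^2 = 0.01 F/m^2
}

#' Simulate the two-domain stimulation model
#'
#' Integrates the coupled attached/free membrane system: the free membrane
#' (area `A_MJ`) lies between the intracellular node `V_I` and the grounded
#' bath, the attached membrane (area `A_J`) between `V_I` and the cleft node
#' `V_J`, which drains to the bath through `R_J`.  Each domain's gating is
#' driven by its own membrane voltage and the channel population is split in
#' proportion to area (uniform density).  `C_M` is converted to the specific
#' capacitance `C_M / A_M`; the background conductance is likewise split per
#' area.  The photostimulus enters the cleft node either as a prescribed
#' source voltage behind the electrode capacitance `C_E` or as an injected
#' photocurrent.
#'
#' In `"vc"` mode the pipette node is held at the sampled command voltage
#' through `R_S` and the Bessel-filtered output current is returned; in
#' `"cc"` mode (I = 0) the pipette is an ideal follower and `V_I` is
#' returned.
#'
#' @param mode `"vc"` (voltage clamp) or `"cc"` (current clamp, I = 0)
#' @param protocol data.frame with columns `t`, `v_cmd`, `light` (from
#'   [sample_protocol()]); in `"cc"` mode `v_cmd` is ignored
#' @param patch a [patch_params()]
#' @param geom a [two_domain_geometry()]
#' @param cleft a [cleft_params()]
#' @param channels a [channel_population()]
#' @param rates a [rate_params()]
#' @param stimulus a [photostimulus()] object, or NULL for no stimulus; its
#'   waveform is gated by the protocol's light trace timing
#' @param filter a [filter_spec()] or NULL
#' @param V0 initial intracellular voltage; default: clamped equilibrium
#'   (vc) or resting equilibrium (cc) at the first sample
#' @param h_max maximum integrator substep (s)
#' @param cell_id,step_level sweep metadata
#' @return list with elements `sweep` (a [new_sweep()]), `state`
#'   (data.frame with `t`, `V_I`, `V_J`, `V_M_attached`, `V_M_free`,
#'   `G_attached`, `G_free`, `i_attached`, `i_stim`, `p_open_attached`,
#'   `p_open_free`) and `params` (resolved parameter echo)
#' @export
simulate_two_domain <- function(mode = c("vc", "cc"), protocol, patch, geom,
                                cleft, channels, rates = kv13_rates(),
                                stimulus = NULL, filter = filter_spec(),
                                V0 = NULL, h_max = 2e-5,
                                cell_id = NA_character_,
                                step_level = NA_real_) {
  mode <- match.arg(mode)
  stopifnot(inherits(patch, "patch_params"),
            inherits(geom, "two_domain_geometry"),
            inherits(cleft, "cleft_params"),
            inherits(channels, "channel_population"),
            inherits(rates, "rate_params"))
  if (rates$n_closed != 4L)
    stop("the compiled integrator supports the 4-closed-state chain")
  t <- protocol$t
  dt <- t[2] - t[1]
  fs <- 1 / dt
  li <- if (!is.null(protocol$light)) protocol$light else rep(0, length(t))

  cm <- patch$C_M / geom$A_M          # specific capacitance (F/m^2)
  gb <- (1 / patch$R_B) / geom$A_M    # specific background conductance
  CE <- resolve_CE(cleft, geom)
  Ng <- channels$N * channels$g
  Ng_att <- Ng * geom$fraction
  Ng_free <- Ng * (1 - geom$fraction)

  stim_mode <- 0L
  vin <- numeric(0); dvin <- numeric(0); iph <- numeric(0)
  if (!is.null(stimulus)) {
    stopifnot(inherits(stimulus, "photostimulus"))
    w <- stimulus_waveform(stimulus, t)
    if (stimulus$mode == "voltage") {
      stim_mode <- 1L; vin <- w$value; dvin <- w$deriv
    } else {
      stim_mode <- 2L; iph <- w$value
    }
    if (geom$A_J < 1e-9 * geom$A_M)
      warning("attached area is essentially zero; the stimulus is decoupled from the cell")
  }

  vc0 <- if (mode == "vc") protocol$v_cmd[1] else NA
  if (is.null(V0)) {
    eq <- two_domain_equilibrium(mode, vc0, patch, geom, cleft, channels,
                                 rates)
    V0 <- eq$V_I; VJ0 <- eq$V_J
  } else VJ0 <- 0
  p0_att <- steady_state(V0 - VJ0, rates)
  p0_free <- steady_state(V0, rates)
  u <- if (mode == "vc") protocol$v_cmd else rep(0, length(t))

  res <- cpp_simulate_two(t, u, if (mode == "vc") 0L else 1L,
                          as_rate_list(rates),
                          Ng_att, Ng_free, channels$E_K,
                          cm * geom$A_J, cm * geom$A_MJ,
                          gb * geom$A_J, gb * geom$A_MJ, patch$E_VHEK,
                          patch$R_S, patch$R_seal, cleft$R_J, CE,
                          stim_mode, vin, dvin, iph,
                          p0_att, p0_free, V0, VJ0, solver_substeps(dt, h_max))
  for (nm in c("V_I", "V_J", "I_out", "G_att", "G_free", "i_att", "i_stim"))
    res[[nm]] <- as.vector(res[[nm]])
  if (any(!is.finite(res$V_I)))
    stop("two-domain integration produced non-finite state")

  state <- data.frame(t = t, V_I = res$V_I, V_J = res$V_J,
                      V_M_attached = res$V_I - res$V_J,
                      V_M_free = res$V_I,
                      G_attached = res$G_att, G_free = res$G_free,
                      i_attached = res$i_att, i_stim = res$i_stim,
                      p_open_attached = res$p_att[, 5],
                      p_open_free = res$p_free[, 5])
  if (mode == "vc") {
    i_f <- if (is.null(filter)) res$I_out else apply_filter(res$I_out, fs, filter)
    sw <- new_sweep(t, protocol$v_cmd, li, i_out = i_f, mode = "vc",
                    cell_id = cell_id, step_level = step_level)
    attr(sw, "i_raw") <- res$I_out
  } else {
    sw <- new_sweep(t, rep(NA_real_, length(t)), li, v_i = res$V_I,
                    mode = "cc", cell_id = cell_id)
  }
  attr(sw, "v_m") <- res$V_I
  list(sweep = sw, state = state,
       params = list(R_J = cleft$R_J, C_E = CE, fraction = geom$fraction,
                     A_M = geom$A_M, mode = mode))
}

# coupled (V_I, V_J) equilibrium of the two-domain circuit without stimulus:
# fixed-point iteration on the linear node equations with the gating at the
# steady state of each domain's membrane voltage
two_domain_equilibrium <- function(mode, vc, patch, geom, cleft, channels,
                                   rates, tol = 1e-13, max_iter = 200) {
  gb <- (1 / patch$R_B) / geom$A_M
  ga <- gb * geom$A_J; gf <- gb * geom$A_MJ
  Ng <- channels$N * channels$g
  Ng_att <- Ng * geom$fraction; Ng_free <- Ng * (1 - geom$fraction)
  EK <- channels$E_K; EV <- patch$E_VHEK
  VI <- if (mode == "vc") clamp_equilibrium(vc, patch, channels, rates)
        else cc_equilibrium(patch, channels, rates)
  VJ <- 0
  for (it in seq_len(max_iter)) {
    pOa <- steady_state(VI - VJ, rates)[rates$n_closed + 1L]
    pOf <- steady_state(VI, rates)[rates$n_closed + 1L]
    Gma <- Ng_att * pOa; Gmf <- Ng_free * pOf
    k11 <- gf + Gmf + ga + Gma + if (mode == "vc") 1 / patch$R_S else 0
    k12 <- -(ga + Gma)
    c1 <- gf * EV + Gmf * EK + ga * EV + Gma * EK +
      if (mode == "vc") vc / patch$R_S else 0
    k21 <- ga + Gma
    k22 <- -(1 / cleft$R_J + ga + Gma)
    c2 <- ga * EV + Gma * EK
    x <- solve(matrix(c(k11, k12, k21, k22), 2, 2, byrow = TRUE), c(c1, c2))
    if (max(abs(x - c(VI, VJ))) < tol) { VI <- x[1]; VJ <- x[2]; break }
    VI <- x[1]; VJ <- x[2]
  }
  list(V_I = VI, V_J = VJ)
}

# resting equilibrium (current clamp I = 0, ideal follower)
cc_equilibrium <- function(patch, channels, rates) {
  GB <- 1 / patch$R_B
  Ng <- channels$N * channels$g
  f <- function(V) {
    pO <- steady_state(V, rates)[rates$n_closed + 1L]
    -GB * (V - patch$E_VHEK) - Ng * pO * (V - channels$E_K)
  }
  uniroot(f, c(min(channels$E_K, patch$E_VHEK) - 0.02,
               max(channels$E_K, patch$E_VHEK) + 0.02), tol = 1e-12)$root
}

#' Equivalent clamp voltage from a measured current trace
#'
#' Computes the command-voltage time course `V_C'(t)` that would reproduce a
#' given output current in the single-domain circuit without any cleft
#' stimulus: at each sample the output relation
#' `I_out = (V_C - V_I)/R_S + V_C/R_seal` is inverted algebraically for
#' `V_C`, and the membrane state (voltage and gating) is advanced under the
#' recovered drive.  Feeding back the unfiltered current of a known
#' simulation reproduces its command voltage to machine precision
#' (round-trip property).
#'
#' @param i_out measured current trace (A); should be the unfiltered output
#'   relation.  With `defilter = TRUE` the discrete Bessel filter is inverted
#'   first (useful for filtered recordings; amplifies high-frequency noise)
#' @param t time grid (s)
#' @param patch a [patch_params()]
#' @param channels a [channel_population()]
#' @param rates a [rate_params()]
#' @param V0 initial membrane voltage (default: consistent with the first
#'   recovered command sample); `p0` initial gating state (default: steady
#'   state at `V0`)
#' @param p0 see `V0`
#' @param defilter logical; invert the recording filter before inversion
#' @param filter a [filter_spec()] used when `defilter = TRUE`
#' @param h_max maximum integrator substep (s)
#' @return data.frame with columns `t`, `v_c_prime` (V), `v_i` (V)
#' @export
equivalent_clamp_voltage <- function(i_out, t, patch, channels,
                                     rates = kv13_rates(), V0 = NULL,
                                     p0 = NULL, defilter = FALSE,
                                     filter = filter_spec(), h_max = 2e-5) {
  stopifnot(inherits(patch, "patch_params"),
            inherits(channels, "channel_population"))
  Ng <- channels$N * channels$g
  if (Ng <= 0 && !is.finite(patch$R_seal))
    stop("output relation is not invertible without a conductance path")
  dt <- t[2] - t[1]
  x <- i_out
  if (defilter) {
    ba <- bessel_digital(filter, 1 / dt)
    x <- as.numeric(signal::filter(ba$a, ba$b, x))
  }
  if (is.null(V0)) {
    # assume the record starts in steady state: V_C constant before t[1]
    kout <- 1 / patch$R_S + 1 / patch$R_seal
    GB <- 1 / patch$R_B
    f <- function(V) {
      pO <- steady_state(V, rates)[rates$n_closed + 1L]
      vc <- (x[1] + V / patch$R_S) / kout
      (vc - V) / patch$R_S - GB * (V - patch$E_VHEK) -
        Ng * pO * (V - channels$E_K)
    }
    V0 <- uniroot(f, c(-0.3, 0.3), tol = 1e-12)$root
  }
  if (is.null(p0)) p0 <- steady_state(V0, rates)
  res <- cpp_invert_single(t, x, as_rate_list(rates), Ng, channels$E_K,
                           patch$C_M, patch$R_S, patch$R_seal, 1 / patch$R_B,
                           patch$E_VHEK, p0, V0, solver_substeps(dt, h_max))
  data.frame(t = t, v_c_prime = as.vector(res$V_C), v_i = as.vector(res$V_I))
}

#' Light-induced conductance increase of the attached membrane
#'
#' Returns `G_attached(t)` minus its pre-stimulus baseline, where
#' `G_attached = N_attached * g * p_O,attached` (the attached-domain Kv1.3
#' conductance).
#'
#' @param state the `state` trajectory returned by [simulate_two_domain()]
#' @param baseline_window time window (s) defining the pre-stimulus baseline;
#'   default: everything before the first nonzero `i_stim` sample (or the
#'   first 10 samples when no stimulus is present)
#' @return data.frame with `t` and `delta_G` (S)
#' @export
conductance_increase <- function(state, baseline_window = NULL) {
  if (is.null(baseline_window)) {
    k <- which(abs(state$i_stim) > 0)
    idx <- if (length(k)) seq_len(max(1L, k[1] - 1L)) else seq_len(min(10L, nrow(state)))
  } else {
    idx <- which(state$t >= baseline_window[1] & state$t <= baseline_window[2])
    if (!length(idx)) stop("baseline window contains no samples")
  }
  base <- mean(state$G_attached[idx])
  data.frame(t = state$t, delta_G = state$G_attached - base)
}

#' Adaptive-ODE reference for the two-domain model
#'
#' Same circuit as [simulate_two_domain()] integrated by `deSolve::lsoda`
#' on the mass-matrix form; independent cross-check of the compiled scheme.
#'
#' @inheritParams simulate_two_domain
#' @param rtol,atol tolerances
#' @return list with `t`, `V_I`, `V_J`
#' @export
simulate_two_domain_ode <- function(mode = c("vc", "cc"), protocol, patch,
                                    geom, cleft, channels,
                                    rates = kv13_rates(), stimulus = NULL,
                                    V0 = NULL, rtol = 1e-8, atol = 1e-10) {
  mode <- match.arg(mode)
  t <- protocol$t
  cm <- patch$C_M / geom$A_M
  gb <- (1 / patch$R_B) / geom$A_M
  CE <- resolve_CE(cleft, geom)
  Ca <- cm * geom$A_J; Cf <- cm * geom$A_MJ
  ga <- gb * geom$A_J; gf <- gb * geom$A_MJ
  Ng_att <- channels$N * channels$g * geom$fraction
  Ng_free <- channels$N * channels$g * (1 - geom$fraction)
  EK <- channels$E_K; EV <- patch$E_VHEK
  vcf <- approxfun(t, protocol$v_cmd, method = "constant", rule = 2)
  stim_mode <- 0L
  sfun <- function(tt) 0
  if (!is.null(stimulus)) {
    if (stimulus$mode == "voltage") {
      stim_mode <- 1L
      sfun <- function(tt) CE * stimulus_deriv_at(stimulus, tt)
    } else {
      stim_mode <- 2L
      sfun <- function(tt) stimulus_value_at(stimulus, tt)
    }
  }
  CEeff <- if (stim_mode == 1L) CE else 0
  M <- matrix(c(Cf + Ca, -Ca, Ca, -(Ca + CEeff)), 2, 2, byrow = TRUE)
  Minv <- solve(M)
  if (is.null(V0)) {
    eq <- two_domain_equilibrium(mode, protocol$v_cmd[1], patch, geom, cleft,
                                 channels, rates)
    V0 <- eq$V_I; VJ0 <- eq$V_J
  } else VJ0 <- 0
  y0 <- c(V0, VJ0, steady_state(V0 - VJ0, rates), steady_state(V0, rates))
  rhs <- function(tt, y, parms) {
    VI <- y[1]; VJ <- y[2]
    pa <- y[3:7]; pf <- y[8:12]
    Gma <- Ng_att * pa[5]; Gmf <- Ng_free * pf[5]
    s <- sfun(tt)
    k11 <- gf + Gmf + ga + Gma + if (mode == "vc") 1 / patch$R_S else 0
    k12 <- -(ga + Gma)
    c1 <- gf * EV + Gmf * EK + ga * EV + Gma * EK +
      if (mode == "vc") vcf(tt) / patch$R_S else 0
    k21 <- ga + Gma
    k22 <- -(1 / cleft$R_J + ga + Gma)
    c2 <- ga * EV + Gma * EK - s
    K <- matrix(c(k11, k12, k21, k22), 2, 2, byrow = TRUE)
    xd <- Minv %*% (-K %*% c(VI, VJ) + c(c1, c2))
    dpa <- as.vector(pa %*% rate_matrix(VI - VJ, rates))
    dpf <- as.vector(pf %*% rate_matrix(VI, rates))
    list(c(xd[1], xd[2], dpa, dpf))
  }
  sol <- deSolve::lsoda(y0, t, rhs, parms = NULL, rtol = rtol, atol = atol,
                        maxsteps = 100000)
  list(t = t, V_I = sol[, 2], V_J = sol[, 3])
}
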