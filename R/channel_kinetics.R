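#' Gating rate parameters for the sequential Kv1.3 Markov model
#'
#' The channel is modelled as a reversible chain of closed states
#' `C0 <-> C1 <-> ... <-> C{nc-1}` followed by a final voltage-independent
#' transition `C{nc-1} <-> O`.  Transitions between closed states occur at the
#' voltage-dependent rates `alpha(V) = alpha1 * exp(V/m)` (forward) and
#' `beta(V) = beta1 * exp(-V/n)` (backward); the last closed state opens at
#' the constant rate `A` and the open state closes at `B`.  The slope voltages
#' `m = R*T/(alpha2*F)` and `n = R*T/(beta2*F)` absorb temperature and the
#' elementary gating charge.
#'
#' @param alpha1 forward rate at 0 V (s^-1)
#' @param m forward slope voltage (V), > 0
#' @param beta1 backward rate at 0 V (s^-1)
#' @param n backward slope voltage (V), > 0
#' @param A closed-to-open rate (s^-1), voltage independent
#' @param B open-to-closed rate (s^-1), voltage independent
#' @param temperature temperature (K); recordings were done at room
#'   temperature, default 293.15 K
#' @param n_closed number of closed states in the chain (default 4)
#' @return object of class `rate_params`
#' @seealso [kv13_rates()] for the fitted TagRFP-Kv1.3 parameter set
#' @export
rate_params <- function(alpha1, m, beta1, n, A, B,
                        temperature = 293.15, n_closed = 4L) {
  vals <- c(alpha1 = alpha1, m = m, beta1 = beta1, n = n, A = A, B = B,
            temperature = temperature)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all rate parameters, slope voltages and the temperature must be finite and > 0")
  if (n_closed < 1) stop("n_closed must be >= 1")
  structure(list(alpha1 = alpha1, m = m, beta1 = beta1, n = n, A = A, B = B,
                 temperature = temperature, n_closed = as.integer(n_closed)),
            class = "rate_params")
}

#' Fitted TagRFP-Kv1.3 gating parameter set
#'
#' Rate constants fitted to whole-cell activation/deactivation recordings of
#' TagRFP-Kv1.3 heterologously expressed in HEK293 cells, used as the default
#' parameter set throughout the package.
#'
#' @param temperature temperature (K)
#' @return a [rate_params()] object
#' @export
kv13_rates <- function(temperature = 293.15) {
  rate_params(alpha1 = 281.4283, m = 0.0255, beta1 = 120, n = 0.5623,
              A = 4.4432e4, B = 9.6566e3, temperature = temperature)
}

as_rate_list <- function(params) {
  stopifnot(inherits(params, "rate_params"))
  params[c("alpha1", "m", "beta1", "n", "A", "B")]
}

check_exp_arg <- function(x) {
  if (any(abs(x) > 700))
    stop("rate-law exponent overflow: |V/slope| > 700")
  invisible(x)
}

#' Voltage-dependent transition rates
#'
#' `forward_rate()` evaluates `alpha(V) = alpha1 * exp(V/m)` (strictly
#' increasing in V), `backward_rate()` evaluates `beta(V) = beta1 * exp(-V/n)`
#' (strictly decreasing).  Arguments with `|V/slope| > 700` raise an error
#' rather than overflow.
#'
#' @param V membrane voltage (V), vectorised
#' @param params a [rate_params()] object
#' @return rate(s) in s^-1
#' @export
forward_rate <- function(V, params) {
  stopifnot(inherits(params, "rate_params"))
  check_exp_arg(V / params$m)
  params$alpha1 * exp(V / params$m)
}

#' @rdname forward_rate
#' @export
backward_rate <- function(V, params) {
  stopifnot(inherits(params, "rate_params"))
  check_exp_arg(V / params$n)
  params$beta1 * exp(-V / params$n)
}

#' State names of the gating chain
#' @param params a [rate_params()] object
#' @return character vector, e.g. `c("C0","C1","C2","C3","O")`
#' @export
state_names <- function(params) {
  c(paste0("C", seq_len(params$n_closed) - 1L), "O")
}

#' Infinitesimal generator of the gating chain
#'
#' Builds the generator matrix Q (s^-1) of the chain at membrane voltage `V`:
#' `Q[i, j]` is the transition rate from state i to state j, rows sum to zero.
#'
#' @inheritParams forward_rate
#' @return square matrix with `n_closed + 1` rows, dimnames set to the states
#' @export
rate_matrix <- function(V, params) {
  stopifnot(inherits(params, "rate_params"), length(V) == 1)
  nc <- params$n_closed
  ns <- nc + 1L
  a <- forward_rate(V, params)
  b <- backward_rate(V, params)
  Q <- matrix(0, ns, ns, dimnames = list(state_names(params), state_names(params)))
  for (i in seq_len(nc - 1L)) {
    Q[i, i + 1L] <- a
    Q[i + 1L, i] <- b
  }
  Q[nc, ns] <- params$A
  Q[ns, nc] <- params$B
  diag(Q) <- -rowSums(Q)
  Q
}

#' Construct / validate a gating-state probability vector
#'
#' @param p numeric probability vector over the chain states
#' @return `p`, validated (entries in `[0, 1]`, sum within 1e-9 of 1)
#' @export
gating_state <- function(p) {
  if (any(p < -1e-12) || any(p > 1 + 1e-12))
    stop("gating-state probabilities must lie in [0, 1]")
  if (abs(sum(p) - 1) > 1e-9)
    stop("gating-state probabilities must sum to 1 (|sum - 1| <= 1e-9)")
  p
}

#' Steady-state occupancy of the gating chain
#'
#' Solves the null-space problem `p Q = 0`, `sum(p) = 1` by least squares on
#' the augmented system.  For this reversible chain the result coincides with
#' the detailed-balance closed form `p[i+1]/p[i] = alpha/beta`,
#' `p[O]/p[C_last] = A/B`.
#'
#' @inheritParams forward_rate
#' @return named probability vector (a valid [gating_state()])
#' @export
steady_state <- function(V, params) {
  Q <- rate_matrix(V, params)
  ns <- nrow(Q)
  A <- rbind(t(Q), rep(1, ns))
  b <- c(rep(0, ns), 1)
  p <- tryCatch(qr.solve(A, b),
                error = function(e) stop("steady-state solve failed (singular generator at V = ",
                                         V, " V): ", conditionMessage(e)))
  p <- pmax(p, 0)
  p <- p / sum(p)
  gating_state(setNames(p, rownames(Q)))
}

#' Propagate the gating master equation along a voltage trajectory
#'
#' Integrates `dp/dt = p Q(V(t))` on the time grid `t`.  With
#' `method = "matrix_exponential"` the voltage must be piecewise constant
#' (numeric vector on the grid, left-closed/right-open segments); each
#' interval is then advanced by the exact propagator `expm(Q dt)`.  With
#' `method = "adaptive_ode"` the trajectory is integrated by `deSolve::lsoda`
#' and `V_of_t` may also be a function of time.
#'
#' @param p0 initial probability vector (validated by [gating_state()])
#' @param t time grid (s), strictly increasing
#' @param V_of_t voltage trajectory: numeric vector on `t` (piecewise
#'   constant) or a function `V(t)` (adaptive_ode only)
#' @param params a [rate_params()] object
#' @param method `"matrix_exponential"` or `"adaptive_ode"`
#' @param rtol,atol integration tolerances for the adaptive method
#' @return matrix of probabilities, one row per output time, columns named by
#'   state; probability is conserved within 1e-9 at all output times
#' @export
propagate <- function(p0, t, V_of_t, params,
                      method = c("matrix_exponential", "adaptive_ode"),
                      rtol = 1e-10, atol = 1e-12) {
  method <- match.arg(method)
  p0 <- gating_state(p0)
  stopifnot(length(t) >= 1, all(diff(t) > 0))
  ns <- params$n_closed + 1L
  if (length(p0) != ns) stop("p0 has wrong length for this chain")

  if (method == "matrix_exponential") {
    if (!is.numeric(V_of_t))
      stop("matrix_exponential requires a piecewise-constant voltage vector on the time grid")
    if (length(V_of_t) != length(t)) stop("V_of_t length != time grid length")
    if (params$n_closed == 4L) {
      P <- cpp_propagate_pc(t, V_of_t, p0, as_rate_list(params))
    } else {
      P <- matrix(0, length(t), ns)
      p <- p0
      for (k in seq_along(t)) {
        P[k, ] <- p
        if (k == length(t)) break
        E <- expm_mat(rate_matrix(V_of_t[k], params) * (t[k + 1] - t[k]))
        p <- as.vector(p %*% E)
      }
    }
  } else {
    Vfun <- if (is.function(V_of_t)) V_of_t
            else approxfun(t, V_of_t, method = "constant", rule = 2)
    rhs <- function(tt, y, parms) {
      list(as.vector(y %*% rate_matrix(Vfun(tt), params)))
    }
    sol <- deSolve::lsoda(y = p0, times = t, func = rhs, parms = NULL,
                          rtol = rtol, atol = atol)
    P <- unname(sol[, -1, drop = FALSE])
  }
  colnames(P) <- state_names(params)
  bad <- abs(rowSums(P) - 1) > 1e-9
  if (any(bad))
    stop("probability conservation violated at ", sum(bad), " output times")
  P
}

# dense matrix exponential by scaling and squaring of a truncated Taylor
# series; used only on the small generators of non-default topologies
expm_mat <- function(M) {
  nrm <- max(rowSums(abs(M)))
  j <- max(0L, ceiling(log2(max(nrm, 1e-300))) + 1L)
  Ms <- M / 2^j
  ns <- nrow(M)
  X <- diag(ns); S <- diag(ns); fac <- 1
  for (q in 1:12) {
    fac <- fac * q
    X <- X %*% Ms
    S <- S + X / fac
  }
  for (q in seq_len(j)) S <- S %*% S
  S
}

#' Channel population: count, unitary conductance, reversal potential
#'
#' @param N number of channels in the cell (fitted as a real number)
#' @param g single-channel conductance (S); the default 12 pS is a nominal
#'   value — only the product `N * g` is ever compared with data, and the
#'   per-cell fit of `N` absorbs `g`
#' @param E_K potassium reversal potential (V); the measured value is -73 mV
#' @return object of class `channel_population`
#' @export
channel_population <- function(N = 12000, g = 12e-12, E_K = -0.073) {
  if (N < 0) stop("channel count N must be >= 0")
  if (g <= 0) stop("single-channel conductance g must be > 0")
  structure(list(N = N, g = g, E_K = E_K), class = "channel_population")
}

#' Macroscopic channel current and conductance
#'
#' `channel_current()` returns `I = N * g * p_O * (V - E_K)` (A);
#' `channel_conductance()` returns `G = N * g * p_O` (S), the whole-cell
#' Kv1.3 conductance `G_M`.
#'
#' @param p_O open probability (vectorised)
#' @param V membrane voltage (V)
#' @param pop a [channel_population()]
#' @return current (A) / conductance (S)
#' @export
channel_current <- function(p_O, V, pop) {
  stopifnot(inherits(pop, "channel_population"))
  pop$N * pop$g * p_O * (V - pop$E_K)
}

#' @rdname channel_current
#' @export
channel_conductance <- function(p_O, pop) {
  stopifnot(inherits(pop, "channel_population"))
  pop$N * pop$g * p_O
}
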