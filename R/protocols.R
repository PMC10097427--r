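#' Voltage step protocols
#'
#' A voltage protocol is an ordered list of `(duration, level)` segments with
#' left-closed/right-open semantics.  `step_family()` expands a protocol
#' template over a family of step levels (one sweep per level).
#'
#' @param durations segment durations (s), all > 0
#' @param levels segment voltage levels (V), same length
#' @return object of class `voltage_protocol`
#' @export
voltage_protocol <- function(durations, levels) {
  stopifnot(length(durations) == length(levels))
  if (any(durations <= 0)) stop("segment durations must be > 0")
  structure(list(durations = durations, levels = levels),
            class = "voltage_protocol")
}

#' @rdname voltage_protocol
#' @param hold holding potential (V) and its duration `hold_s` (s)
#' @param hold_s see `hold`
#' @param step_s step duration (s)
#' @param from,to,by step family range and increment (V); `by` must divide
#'   the span
#' @export
step_family <- function(hold, hold_s, step_s, from, to, by) {
  nstep <- (to - from) / by
  if (abs(nstep - round(nstep)) > 1e-9)
    stop("step increment must divide the span")
  levels <- from + by * (0:round(nstep))
  lapply(levels, function(v) {
    p <- voltage_protocol(c(hold_s, step_s), c(hold, v))
    p$step_level <- v
    p
  })
}

#' Light pulse protocol
#'
#' @param onset pulse onsets (s, absolute protocol time)
#' @param duration pulse durations (s)
#' @param intensity pulse intensities (mW mm^-2), >= 0
#' @return object of class `light_protocol`
#' @export
light_protocol <- function(onset = numeric(0), duration = numeric(0),
                           intensity = numeric(0)) {
  k <- length(onset)
  stopifnot(length(duration) == k, length(intensity) == k)
  if (any(intensity < 0)) stop("light intensity must be >= 0")
  if (k > 1) {
    o <- order(onset)
    if (any(onset[o][-1] < (onset + duration)[o][-k]))
      stop("light pulses must not overlap")
  }
  structure(list(onset = onset, duration = duration, intensity = intensity),
            class = "light_protocol")
}

#' Whole-cell Kv1.3 activation protocol (HEK293)
#'
#' Hold at -100 mV for 2.5 s, then a 400 ms depolarisation step swept from
#' -100 to +40 mV in 10 mV increments (15 sweeps).  A 5 ms light pulse is
#' applied 20 ms after step onset.
#'
#' @param intensity light intensity (mW mm^-2); 0 disables the pulse
#' @param hold_s holding duration (s); the full 2.5 s hold mainly serves to
#'   reset gating between sweeps, so analyses that start from the holding
#'   steady state may shorten it
#' @param step_s step duration (s)
#' @return list with elements `voltage` (list of per-sweep
#'   [voltage_protocol()]s) and `light` (a [light_protocol()], onsets relative
#'   to the shared protocol clock)
#' @export
hek_activation_protocol <- function(intensity = 13, hold_s = 2.5,
                                    step_s = 0.4) {
  fam <- step_family(hold = -0.100, hold_s = hold_s, step_s = step_s,
                     from = -0.100, to = 0.040, by = 0.010)
  lp <- if (intensity > 0)
    light_protocol(onset = hold_s + 0.020, duration = 0.005,
                   intensity = intensity)
  else light_protocol()
  list(voltage = fam, light = lp)
}

#' Neuron voltage-step protocol
#'
#' Hold at -70 mV for 3 s, then a 500 ms depolarisation step swept from
#' -70 to +20 mV in 5 mV increments (19 sweeps); light pulse 20 ms after
#' step onset with configurable length and intensity.
#'
#' @param intensity light intensity (mW mm^-2)
#' @param pulse_s light pulse duration (s)
#' @param hold_s,step_s hold and step durations (s)
#' @export
neuron_step_protocol <- function(intensity = 26, pulse_s = 0.020,
                                 hold_s = 3, step_s = 0.5) {
  fam <- step_family(hold = -0.070, hold_s = hold_s, step_s = step_s,
                     from = -0.070, to = 0.020, by = 0.005)
  lp <- if (intensity > 0)
    light_protocol(onset = hold_s + 0.020, duration = pulse_s,
                   intensity = intensity)
  else light_protocol()
  list(voltage = fam, light = lp)
}

#' Sample a protocol onto a uniform time grid
#'
#' Produces the sampled command-voltage and light-intensity traces for one
#' sweep.  The sampling rate must place every segment and pulse edge on a
#' grid point; segments are left-closed/right-open.
#'
#' @param protocol a [voltage_protocol()]
#' @param light a [light_protocol()] (or NULL)
#' @param fs sampling rate (Hz)
#' @return data.frame with columns `t` (s), `v_cmd` (V), `light`
#'   (mW mm^-2); the grid covers `[0, total_duration)`
#' @export
sample_protocol <- function(protocol, light = NULL, fs) {
  stopifnot(inherits(protocol, "voltage_protocol"), fs > 0)
  edges <- cumsum(c(0, protocol$durations))
  total <- edges[length(edges)]
  nsamp <- total * fs
  if (abs(nsamp - round(nsamp)) > 1e-6)
    stop("sampling rate does not place the protocol end on a grid point")
  check_on_grid <- function(x, what) {
    k <- x * fs
    if (any(abs(k - round(k)) > 1e-6))
      stop(what, " edges must coincide with sample instants at fs = ", fs)
  }
  check_on_grid(edges, "segment")
  t <- seq_len(round(nsamp)) / fs - 1 / fs
  seg <- findInterval(t * fs + 0.5, edges * fs)  # half-sample shift: robust edge snap
  v <- protocol$levels[pmin(seg, length(protocol$levels))]
  li <- rep(0, length(t))
  if (!is.null(light) && length(light$onset)) {
    check_on_grid(c(light$onset, light$onset + light$duration), "light pulse")
    if (any(light$onset + light$duration > total + 1e-12))
      stop("light pulse extends beyond the protocol span")
    for (j in seq_along(light$onset)) {
      on <- light$onset[j]
      off <- on + light$duration[j]
      li[t >= on - 1e-12 & t < off - 1e-12] <- light$intensity[j]
    }
  }
  data.frame(t = t, v_cmd = v, light = li)
}

#' Serialize / deserialize protocols
#'
#' Protocols round-trip exactly through a YAML representation.
#'
#' @param protocol a [voltage_protocol()]
#' @param light a [light_protocol()] or NULL
#' @param path file path
#' @export
write_protocol <- function(protocol, light = NULL, path) {
  obj <- list(voltage = list(durations_s = protocol$durations,
                             levels_V = protocol$levels))
  if (!is.null(protocol$step_level)) obj$voltage$step_level_V <- protocol$step_level
  if (!is.null(light))
    obj$light <- list(onset_s = light$onset, duration_s = light$duration,
                      intensity_mW_mm2 = light$intensity)
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  obj <- yaml::read_yaml(path)
  vp <- voltage_protocol(as.numeric(obj$voltage$durations_s),
                         as.numeric(obj$voltage$levels_V))
  if (!is.null(obj$voltage$step_level_V))
    vp$step_level <- as.numeric(obj$voltage$step_level_V)
  lp <- if (!is.null(obj$light))
    light_protocol(as.numeric(obj$light$onset_s),
                   as.numeric(obj$light$duration_s),
                   as.numeric(obj$light$intensity_mW_mm2))
  else NULL
  list(voltage = vp, light = lp)
}
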