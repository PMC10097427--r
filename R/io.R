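#' Write / read sweep families as CSV
#'
#' The canonical interchange format is one CSV per family with columns
#' `sweep`, `step_V`, `t_s`, `V_C_V`, `light`, and `I_out_A` (voltage clamp)
#' or `V_I_V` (current clamp).  Millivolt/picoampere column variants
#' (`t_ms`, `V_C_mV`, `I_out_pA`, `V_I_mV`) are converted to SI on read.
#'
#' @param sweeps a list of [new_sweep()]s
#' @param path file path
#' @export
write_sweeps <- function(sweeps, path) {
  fmt <- function(x) sprintf("%.17g", x)   # lossless double round-trip
  rows <- lapply(seq_along(sweeps), function(i) {
    s <- sweeps[[i]]
    df <- data.frame(sweep = i, step_V = fmt(attr(s, "step_level")),
                     t_s = fmt(s$t), V_C_V = fmt(s$v_cmd),
                     light = fmt(s$light))
    if (!is.null(s$i_out)) df$I_out_A <- fmt(s$i_out)
    if (!is.null(s$v_i)) df$V_I_V <- fmt(s$v_i)
    df
  })
  utils::write.table(do.call(rbind, rows), path, row.names = FALSE,
                     quote = FALSE, sep = ",")
  invisible(path)
}

unit_map <- c(t_s = 1, t_ms = 1e-3,
              V_C_V = 1, V_C_mV = 1e-3,
              I_out_A = 1, I_out_pA = 1e-12, I_out_nA = 1e-9,
              V_I_V = 1, V_I_mV = 1e-3)

#' @rdname write_sweeps
#' @param dialect `"csv"` or `"atf"` (Axon Text Format, read-only)
#' @return list of [new_sweep()]s (class `sweep_set`)
#' @export
read_sweeps <- function(path, dialect = c("csv", "atf")) {
  dialect <- match.arg(dialect)
  if (dialect == "atf") return(read_atf(path))
  df <- read.csv(path)
  req_of <- function(prefix) {
    hit <- intersect(names(unit_map)[startsWith(names(unit_map), prefix)],
                     names(df))
    if (length(hit) > 1)
      stop("ambiguous units: multiple '", prefix, "' columns present")
    hit
  }
  tcol <- req_of("t_")
  vcol <- req_of("V_C_")
  icol <- req_of("I_out_")
  wcol <- req_of("V_I_")
  if (!length(tcol)) stop("missing required time column (t_s or t_ms)")
  if (!length(vcol)) stop("missing required command-voltage column (V_C_V or V_C_mV)")
  if (!length(icol) && !length(wcol))
    stop("missing output column (I_out_* or V_I_*)")
  if (is.null(df$sweep)) df$sweep <- 1
  out <- lapply(split(df, df$sweep), function(d) {
    t <- d[[tcol]] * unit_map[[tcol]]
    if (length(t) > 1) {
      dt <- diff(t)
      if (any(dt <= 0) || diff(range(dt)) > 1e-6 * max(dt))
        stop("non-uniform time grid in column '", tcol, "'")
    }
    li <- if (!is.null(d$light)) d$light else rep(0, length(t))
    new_sweep(t, d[[vcol]] * unit_map[[vcol]], li,
              i_out = if (length(icol)) d[[icol]] * unit_map[[icol]],
              v_i = if (length(wcol)) d[[wcol]] * unit_map[[wcol]],
              mode = if (length(icol)) "vc" else "cc",
              step_level = if (!is.null(d$step_V)) d$step_V[1] else NA_real_)
  })
  out <- unname(out)
  class(out) <- c("sweep_set", "list")
  out
}

# Axon Text Format: header line "ATF <major> <minor>", a line with the
# counts of optional-header records and data columns, the optional header
# records, one title line of quoted column names, then tab/space-separated
# numbers.  First column is time in ms, remaining columns one trace per
# sweep (pA assumed unless the title says otherwise).
read_atf <- function(path) {
  lines <- readLines(path)
  if (!grepl("^ATF", lines[1])) stop("not an ATF file: missing ATF signature")
  counts <- scan(text = lines[2], quiet = TRUE)
  n_head <- counts[1]
  title <- lines[3 + n_head]
  cols <- regmatches(title, gregexpr('"[^"]*"', title))[[1]]
  cols <- gsub('"', "", cols)
  dat <- read.table(text = lines[-seq_len(3 + n_head)], header = FALSE)
  t_ms <- dat[[1]]
  t <- t_ms * 1e-3
  to_amp <- function(j) {
    u <- cols[j]
    f <- if (grepl("\\(pA\\)", u)) 1e-12 else if (grepl("\\(nA\\)", u)) 1e-9 else 1
    dat[[j]] * f
  }
  out <- lapply(seq_len(ncol(dat) - 1), function(j) {
    new_sweep(t, rep(NA_real_, length(t)), rep(0, length(t)),
              i_out = to_amp(j + 1), mode = "vc")
  })
  class(out) <- c("sweep_set", "list")
  out
}

#' Run configuration
#'
#' Resolve a pipeline configuration against the package defaults.  Seeds are
#' mandatory.  The resolved configuration (all defaults made explicit) is
#' what [run_pipeline()] echoes into its output directory.
#'
#' @param config named list (or YAML path) with any of: `seed`,
#'   `cell_seed`, `noise_rms`, `fs`, `intensity`, `hold_s`, `step_s`,
#'   `swarm_size`, `n_iter`, `fit`, `out_dir`
#' @return resolved configuration list
#' @export
resolve_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(seed = NULL, cell_seed = NULL, noise_rms = 0.02,
                   fs = 10000, intensity = 13, hold_s = 0.02, step_s = 0.1,
                   swarm_size = 40, n_iter = 60, fit = TRUE,
                   out_dir = "oepcsim-run")
  cfg <- modifyList(defaults, config)
  if (is.null(cfg$seed)) stop("configuration must provide a seed")
  if (is.null(cfg$cell_seed)) cfg$cell_seed <- cfg$seed
  cfg
}

#' Run the synthetic pipeline end to end
#'
#' Executes synth -> simulate -> fit -> G-V analysis on a synthetic cell and
#' writes all artifacts (resolved config, sweep CSVs, fit JSON, G-V table,
#' log with seeds and package version) into the output directory.
#'
#' @param config see [resolve_config()]
#' @return (invisibly) the output directory path
#' @export
run_pipeline <- function(config = list()) {
  cfg <- resolve_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(cfg$out_dir, "run.log")
  logline <- function(...) cat(format(Sys.time(), "%H:%M:%S "), ...,
                               "\n", sep = "", file = logf, append = TRUE)
  cat("", file = logf)
  yaml::write_yaml(cfg, file.path(cfg$out_dir, "resolved_config.yaml"))
  logline("oepcsim ", as.character(packageVersion("oepcsim")),
          " seed=", cfg$seed, " cell_seed=", cfg$cell_seed)

  cell <- generate_cell(cfg$cell_seed)
  act <- hek_activation_protocol(intensity = 0, hold_s = cfg$hold_s,
                                 step_s = cfg$step_s)
  sweeps <- generate_sweeps(cell, act$voltage, light = NULL,
                            noise_rms = cfg$noise_rms, fs = cfg$fs,
                            seed = cfg$seed)
  write_sweeps(sweeps, file.path(cfg$out_dir, "sweeps_dark.csv"))
  logline("simulated ", length(sweeps), " activation sweeps, fs=", cfg$fs)

  step_end <- cfg$hold_s + cfg$step_s
  dark <- conductance_from_sweeps(sweeps, window = c(step_end - 0.02,
                                                     step_end - 0.001))
  bf <- boltzmann_fit(dark)
  gv <- data.frame(V = dark$V, G = dark$G, G_norm = dark$G_norm)
  write.csv(gv, file.path(cfg$out_dir, "gv_dark.csv"), row.names = FALSE)
  logline("dark V50 = ", signif(bf$V50 * 1e3, 4), " mV")

  result <- list(cell = list(seed = cell$seed,
                             N = cell$channels$N,
                             C_M = cell$patch$C_M,
                             fraction = cell$geom$fraction),
                 V50_dark = bf$V50, G_max = bf$G_max, slope = bf$slope,
                 package_version = as.character(packageVersion("oepcsim")),
                 seed = cfg$seed)
  if (isTRUE(cfg$fit)) {
    Nhat <- fit_channel_count(sweeps, cell$patch, kv13_rates())
    result$N_fit <- Nhat
    logline("fitted N = ", round(Nhat), " (truth ", round(cell$channels$N), ")")
  }
  jsonlite::write_json(result, file.path(cfg$out_dir, "result.json"),
                       auto_unbox = TRUE, digits = NA)
  logline("done")
  invisible(cfg$out_dir)
}
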