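#' Generate dense Poisson spike trains
#'
#' Independent Bernoulli(`rate * dt`) spikes per timestep per channel —
#' the discrete-time Poisson process that emulates sustained, dense
#' pre- and post-synaptic activity. Reproducible: the same seed always
#' yields the same trains.
#'
#' @param duration Simulation length (s), default 5.
#' @param dt Timestep (s), default 1 ms.
#' @param rate Firing rate per channel (Hz), default 20; `rate * dt`
#'   must not exceed 1.
#' @param seed Integer RNG seed.
#' @return A list of class `spike_scenario` with binary vectors `s_i`,
#'   `s_j` plus `dt`, `duration` and `kind`.
#' @export
gen_dense <- function(duration = 5, dt = 1e-3, rate = 20, seed = 1L) {
  stopifnot(duration > 0, dt > 0, rate >= 0)
  if (rate * dt > 1) stop("rate * dt exceeds 1: more than one spike per bin")
  n <- round(duration / dt)
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old))
  set.seed(seed)
  s_i <- as.numeric(stats::runif(n) < rate * dt)
  s_j <- as.numeric(stats::runif(n) < rate * dt)
  spike_scenario(s_i, s_j, dt, duration, "dense_poisson", seed)
}

#' Generate overlapping burst spike trains
#'
#' Both channels fire Bernoulli(`burst_rate * dt`) spikes inside the
#' same burst windows and are silent elsewhere — the coincident-burst
#' regime in which the synaptic weight rises during activity and decays
#' back to zero in the long silent tail.
#'
#' @param duration Simulation length (s); default 11 (1 s of activity
#'   followed by 10 s of silence).
#' @param dt Timestep (s).
#' @param bursts List of `c(start, end)` windows in seconds, shared by
#'   both channels; default a single `(0, 1)` burst.
#' @param burst_rate Firing rate inside bursts (Hz), default 50.
#' @param seed Integer RNG seed.
#' @return A `spike_scenario` (see [gen_dense()]).
#' @export
gen_overlap <- function(duration = 11, dt = 1e-3,
                        bursts = list(c(0, 1)), burst_rate = 50,
                        seed = 1L) {
  mask <- burst_mask(bursts, duration, dt)
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old))
  set.seed(seed)
  n <- round(duration / dt)
  s_i <- as.numeric(stats::runif(n) < burst_rate * dt) * mask
  s_j <- as.numeric(stats::runif(n) < burst_rate * dt) * mask
  spike_scenario(s_i, s_j, dt, duration, "overlap_bursts", seed)
}

#' Generate temporally separated burst spike trains
#'
#' The two channels burst in disjoint windows — anti-correlated
#' activity under which the synaptic weight dips negative before
#' relaxing back to zero in silence.
#'
#' @param duration Simulation length (s); default 12 (two disjoint 1 s
#'   bursts followed by silence).
#' @param dt Timestep (s).
#' @param bursts_i,bursts_j Lists of `c(start, end)` windows (s) for the
#'   pre- and post-synaptic channel; any overlap between the two sets is
#'   a configuration error.
#' @param burst_rate Firing rate inside bursts (Hz), default 50.
#' @param seed Integer RNG seed.
#' @return A `spike_scenario` (see [gen_dense()]).
#' @export
gen_separated <- function(duration = 12, dt = 1e-3,
                          bursts_i = list(c(0, 1)),
                          bursts_j = list(c(1.5, 2.5)),
                          burst_rate = 50, seed = 1L) {
  mask_i <- burst_mask(bursts_i, duration, dt)
  mask_j <- burst_mask(bursts_j, duration, dt)
  if (any(mask_i & mask_j))
    stop("burst windows of the two channels overlap; use gen_overlap()")
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old))
  set.seed(seed)
  n <- round(duration / dt)
  s_i <- as.numeric(stats::runif(n) < burst_rate * dt) * mask_i
  s_j <- as.numeric(stats::runif(n) < burst_rate * dt) * mask_j
  spike_scenario(s_i, s_j, dt, duration, "separated_bursts", seed)
}

spike_scenario <- function(s_i, s_j, dt, duration, kind, seed = NA) {
  structure(list(s_i = s_i, s_j = s_j, dt = dt, duration = duration,
                 kind = kind, seed = seed),
            class = "spike_scenario")
}

# 0/1 mask of timesteps falling inside any window; bin t covers
# [(t-1) dt, t dt)
burst_mask <- function(windows, duration, dt) {
  n <- round(duration / dt)
  mask <- integer(n)
  for (w in windows) {
    stopifnot(length(w) == 2, w[1] < w[2], w[1] >= 0, w[2] <= duration)
    idx <- which((seq_len(n) - 1) * dt >= w[1] & (seq_len(n) - 1) * dt < w[2])
    mask[idx] <- 1L
  }
  mask
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Score an emulated trace series against the reference
#'
#' Computes, per trace (`z_i`, `z_j`, `p_i`, `p_j`, `p_ij`, `w_ij`,
#' `beta_j`), the mean absolute error, maximum absolute error, RMSE and
#' Pearson correlation between the two series over the full horizon.
#' If both series of a trace are constant, the correlation is reported
#' as 1 when they are equal and `NaN` (with a warning) otherwise, since
#' Pearson correlation is undefined on constant series.
#'
#' @param ref Reference `trace_series` (from [run_reference()]).
#' @param emu Emulated `trace_series` (from [run_emulation()]).
#' @return A `comparison_report` data.frame with one row per trace and
#'   columns `trace`, `mean_error`, `max_error`, `rmse`, `pearson_r`.
#' @export
compare_traces <- function(ref, emu) {
  if (nrow(ref) != nrow(emu))
    stop("trace series have different lengths")
  if (!isTRUE(all.equal(attr(ref, "dt"), attr(emu, "dt"))))
    stop("trace series have different timesteps")
  cols <- trace_columns()
  rows <- lapply(cols, function(cn) {
    d <- emu[[cn]] - ref[[cn]]
    r <- if (all(d == 0) && stats::sd(ref[[cn]]) > 0) {
      1  # identical non-constant series correlate exactly
    } else if (stats::sd(ref[[cn]]) == 0 && stats::sd(emu[[cn]]) == 0) {
      if (all(d == 0)) 1 else {
        warning("constant but unequal '", cn,
                "' series: correlation undefined")
        NaN
      }
    } else if (stats::sd(ref[[cn]]) == 0 || stats::sd(emu[[cn]]) == 0) {
      warning("one constant '", cn, "' series: correlation undefined")
      NaN
    } else {
      stats::cor(ref[[cn]], emu[[cn]])
    }
    data.frame(trace = cn, mean_error = mean(abs(d)),
               max_error = max(abs(d)), rmse = sqrt(mean(d^2)),
               pearson_r = r)
  })
  rep_df <- do.call(rbind, rows)
  attr(rep_df, "n_steps") <- nrow(ref)
  attr(rep_df, "dt") <- attr(ref, "dt")
  attr(rep_df, "variants") <- c(attr(ref, "variant"), attr(emu, "variant"))
  class(rep_df) <- c("comparison_report", "data.frame")
  rep_df
}

#' Write a comparison report
#'
#' Serializes a [compare_traces()] report as JSON, CSV or a markdown
#' table (one row per trace, one column per metric).
#'
#' @param report A `comparison_report`.
#' @param path Output file path.
#' @param format `"json"`, `"csv"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "csv", "markdown")) {
  format <- match.arg(format)
  if (!inherits(report, "comparison_report") || nrow(report) == 0)
    stop("not a populated comparison report")
  if (format == "json") {
    jsonlite::write_json(list(schema = "membcpnn-comparison/1",
                              n_steps = attr(report, "n_steps"),
                              dt = attr(report, "dt"),
                              variants = attr(report, "variants"),
                              metrics = as.data.frame(report)),
                         path, auto_unbox = TRUE, digits = NA)
  } else if (format == "csv") {
    utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  } else {
    fmt <- function(x) formatC(x, digits = 4, format = "f")
    lines <- c("| Trace | Mean error | Max error | RMSE | Correlation |",
               "|---|---|---|---|---|",
               sprintf("| %s | %s | %s | %s | %s |", report$trace,
                       fmt(report$mean_error), fmt(report$max_error),
                       fmt(report$rmse), fmt(report$pearson_r)))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a JSON comparison report
#'
#' @param path Path written by [write_report()] with `format = "json"`.
#' @return The `comparison_report` data.frame.
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rep_df <- as.data.frame(obj$metrics)
  attr(rep_df, "n_steps") <- obj$n_steps
  attr(rep_df, "dt") <- obj$dt
  attr(rep_df, "variants") <- obj$variants
  class(rep_df) <- c("comparison_report", "data.frame")
  rep_df
}
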