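#' Read a spike-train CSV
#'
#' Expects columns `time_step`, `s_i`, `s_j` with binary spike values.
#'
#' @param path CSV file path.
#' @param dt Timestep (s) to attach to the scenario (not stored in the
#'   CSV), default 1 ms.
#' @return A `spike_scenario` (see [gen_dense()]).
#' @export
read_spike_csv <- function(path, dt = 1e-3) {
  df <- utils::read.csv(path)
  need <- c("time_step", "s_i", "s_j")
  if (!all(need %in% names(df)))
    stop("spike CSV must have columns: ", paste(need, collapse = ", "))
  df <- df[order(df$time_step), ]
  s_i <- as.numeric(df$s_i)
  s_j <- as.numeric(df$s_j)
  check_spikes(s_i, s_j)
  spike_scenario(s_i, s_j, dt, length(s_i) * dt, "from_csv")
}

#' Write a spike-train CSV
#'
#' @param scenario A `spike_scenario`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spike_csv <- function(scenario, path) {
  utils::write.csv(data.frame(time_step = seq_along(scenario$s_i),
                              s_i = scenario$s_i, s_j = scenario$s_j),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a trace series to CSV
#'
#' One column per trace, as produced by [run_reference()] or
#' [run_emulation()].
#'
#' @param series A `trace_series` data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' Read a trace series from CSV
#'
#' @param path CSV written by [write_trace_csv()].
#' @param dt Timestep (s); if `NULL`, recovered from the `time` column.
#' @return A `trace_series` data.frame.
#' @export
read_trace_csv <- function(path, dt = NULL) {
  df <- utils::read.csv(path)
  if (is.null(dt)) dt <- if ("time" %in% names(df)) df$time[1] else 1e-3
  trace_series(df, dt = dt, variant = "from_csv")
}

#' Read a model configuration file
#'
#' Reads a YAML or JSON configuration with optional blocks `bcpnn`,
#' `device`, `readout`, `schedule` and `hcu`; keys mirror the argument
#' names of [bcpnn_params()], [device_params()], [readout_chain()] and
#' [pulse_schedule()]. Missing blocks or keys fall back to the package
#' defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `bcpnn`, `device`, `chain`, `schedule`
#'   and `hcu` (a list with `n_pre`, `n_post`, possibly `NULL`).
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("config must be a .yaml/.yml or .json file")
  build <- function(ctor, block) {
    args <- raw[[block]]
    if (is.null(args)) return(ctor())
    known <- names(formals(ctor))
    unknown <- setdiff(names(args), known)
    if (length(unknown) > 0)
      stop("unknown keys in config block '", block, "': ",
           paste(unknown, collapse = ", "))
    do.call(ctor, args)
  }
  list(bcpnn = build(bcpnn_params, "bcpnn"),
       device = build(device_params, "device"),
       chain = build(readout_chain, "readout"),
       schedule = build(pulse_schedule, "schedule"),
       hcu = raw$hcu)
}
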