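# Plain-text run configuration: `section.key = value` lines, SI units
# throughout (seconds, Hz, mm, fractions); display units (ms, %, degrees
# for flip angles) appear only at I/O boundaries.

#' Default run configuration
#'
#' Nested list of every tunable parameter of the simulation, acquisition
#' and analysis chain, with the study protocol as defaults (myocardium
#' tissue, 20 x 20.48 ms / 270 Hz sinc pulses at 3000 Hz and 800 degrees,
#' SPGR 3.8/1.6 ms at 15 degrees, 65 bpm, echo 15 of beat 5).
#'
#' @return A named nested list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    seed = 1234,
    tissue = list(T1_free = 1.1, T2_free = 0.055, T1_bound = 1.0,
                  T2_bound = 14e-6, psr = 0.15, exchange_rate = 50),
    prep = list(delta_f = 3000, mt_flip = 800, n_pulses = 20,
                duration = 20.48e-3, bandwidth = 270, gap = 1.5e-3,
                dt = 50e-6, spoil_in_gap = TRUE),
    imaging = list(variant = "SPGR", TR = 3.8e-3, TE = 1.6e-3, flip = 15,
                   n_startup = 14, echo_index = 15, profiles_per_beat = 30),
    protocol = list(heart_rate = 65, n_heartbeats = 5, b0_offset = 0,
                    measure_beat = 5),
    acquisition = list(n_coils = 4, noise_sd = 0, profiles_per_beat = 30),
    motion = list(period = 4, amplitude_FH = 8, amplitude_LR = 2,
                  drift = 0, nonrigid_amplitude = 0, nonrigid_scale = 60),
    analysis = list(floor = 0.05, smooth_kernel = 5, smooth_sigma = 3,
                    n_bins = 4, max_bin_width = 3.5)),
    class = "run_config")
}

#' Read / write a run configuration
#'
#' The file format is one `section.key = value` assignment per line;
#' `#` starts a comment.  Values are parsed as numeric, logical
#' (`true`/`false`) or string.  Unknown keys are an error, so typos fail
#' before any computation.
#'
#' @param path File path.
#' @return For `read_run_config`, a `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- default_run_config()
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(kv[2])
    parsed <- if (tolower(val) %in% c("true", "false"))
      as.logical(toupper(val))
    else if (!is.na(suppressWarnings(as.numeric(val)))) as.numeric(val)
    else val
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1) {
      if (!parts %in% names(cfg)) stop("unknown config key: ", key)
      cfg[[parts]] <- parsed
    } else if (length(parts) == 2) {
      if (!parts[1] %in% names(cfg) ||
          !parts[2] %in% names(cfg[[parts[1]]]))
        stop("unknown config key: ", key)
      cfg[[parts[1]]][[parts[2]]] <- parsed
    } else stop("unknown config key: ", key)
  }
  validate_run_config(cfg)
  cfg
}

#' @rdname read_run_config
#' @param cfg A `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  lines <- character(0)
  for (sec in names(cfg)) {
    if (!is.list(cfg[[sec]])) {
      lines <- c(lines, sprintf("%s = %s", sec, format(cfg[[sec]])))
    } else {
      for (k in names(cfg[[sec]]))
        lines <- c(lines, sprintf("%s.%s = %s", sec, k,
                                  format(cfg[[sec]][[k]])))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# build validated objects from a config (each constructor re-checks its
# own preconditions)
cfg_tissue <- function(cfg) do.call(tissue_params, cfg$tissue)

cfg_prep <- function(cfg) {
  p <- cfg$prep
  mt_preparation(make_sinc_pulse(p$mt_flip, p$duration, p$bandwidth,
                                 p$dt, p$delta_f),
                 n_pulses = p$n_pulses, gap = p$gap,
                 spoil_in_gap = p$spoil_in_gap)
}

cfg_imaging <- function(cfg) {
  im <- cfg$imaging
  imaging_module(im$variant, im$TR, im$TE, im$flip, im$n_startup,
                 im$echo_index, im$profiles_per_beat)
}

cfg_protocol <- function(cfg) do.call(sim_protocol, cfg$protocol)

validate_run_config <- function(cfg) {
  cfg_tissue(cfg)
  cfg_prep(cfg)
  cfg_imaging(cfg)
  cfg_protocol(cfg)
  invisible(TRUE)
}
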