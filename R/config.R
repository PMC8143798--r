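#' Analysis configuration
#'
#' Bundles every tunable constant of the analysis pipeline. Defaults are the
#' constants used throughout the original study design: the 30--100 ms visual
#' burst interval after stimulus onset, the 0--20 ms intra-saccadic counting
#' window after movement onset, the +/-90 degree toward/opposite direction
#' rule, the cutoff of at least 15 trials per spike-count level together with
#' exclusion of counts above five, the 50 ms / 10 ms running-average amplitude
#' time course, 30-trial sorting bins with a three-consecutive-bin
#' significance rule at Bonferroni-corrected alpha = 0.05, 5-ms spike-count
#' bins over -100..+100 ms around movement onset, the >550 ms post-stimulus
#' rule for sustained-discharge movements, and the 4.5 deg near/far
#' eccentricity split.
#'
#' @param visual_burst_window numeric length-2, ms after stimulus onset.
#' @param intra_saccadic_window numeric length-2, ms after movement onset.
#' @param toward_halfwidth deg; movements within this angular distance of the
#'   RF direction count as "toward".
#' @param min_trials_per_level minimum trials for a spike-count level to enter
#'   the amplitude model.
#' @param max_spike_level largest spike-count level retained.
#' @param timecourse_window,timecourse_step ms; running average of amplitudes.
#' @param sort_bin_size trials per bin in the burst-timing sort.
#' @param consecutive_bins run length declaring onset/offset of significance.
#' @param alpha nominal significance level.
#' @param bonferroni apply Bonferroni correction in the timing sort.
#' @param spike_bin ms; bin width of the peri-saccadic spike time course.
#' @param spike_bin_range numeric length-2, ms around movement onset.
#' @param sustained_min_time ms after stimulus onset defining "sustained"
#'   movements.
#' @param near_eccentricity_max deg; neurons at or below this are "near".
#' @param rate_kernel_sd ms; Gaussian kernel SD for firing-rate curves.
#' @param rng_seed integer or NA; seed recorded alongside results.
#' @return An object of class `analysis_config` (a validated list).
#' @export
analysis_config <- function(visual_burst_window = c(30, 100),
                            intra_saccadic_window = c(0, 20),
                            toward_halfwidth = 90,
                            min_trials_per_level = 15,
                            max_spike_level = 5,
                            timecourse_window = 50,
                            timecourse_step = 10,
                            sort_bin_size = 30,
                            consecutive_bins = 3,
                            alpha = 0.05,
                            bonferroni = TRUE,
                            spike_bin = 5,
                            spike_bin_range = c(-100, 100),
                            sustained_min_time = 550,
                            near_eccentricity_max = 4.5,
                            rate_kernel_sd = 10,
                            rng_seed = NA_integer_) {
  cfg <- list(
    visual_burst_window = as.numeric(visual_burst_window),
    intra_saccadic_window = as.numeric(intra_saccadic_window),
    toward_halfwidth = as.numeric(toward_halfwidth),
    min_trials_per_level = as.integer(min_trials_per_level),
    max_spike_level = as.integer(max_spike_level),
    timecourse_window = as.numeric(timecourse_window),
    timecourse_step = as.numeric(timecourse_step),
    sort_bin_size = as.integer(sort_bin_size),
    consecutive_bins = as.integer(consecutive_bins),
    alpha = as.numeric(alpha),
    bonferroni = isTRUE(as.logical(bonferroni)),
    spike_bin = as.numeric(spike_bin),
    spike_bin_range = as.numeric(spike_bin_range),
    sustained_min_time = as.numeric(sustained_min_time),
    near_eccentricity_max = as.numeric(near_eccentricity_max),
    rate_kernel_sd = as.numeric(rate_kernel_sd),
    rng_seed = suppressWarnings(as.integer(rng_seed))
  )
  validate_analysis_config(cfg)
  class(cfg) <- "analysis_config"
  cfg
}

validate_analysis_config <- function(cfg) {
  ord <- function(w, nm) {
    if (length(w) != 2L || any(!is.finite(w)) || w[1] >= w[2]) {
      stop(sprintf("'%s' must be an ordered pair", nm), call. = FALSE)
    }
  }
  ord(cfg$visual_burst_window, "visual_burst_window")
  ord(cfg$intra_saccadic_window, "intra_saccadic_window")
  ord(cfg$spike_bin_range, "spike_bin_range")
  cnts <- c(cfg$min_trials_per_level, cfg$max_spike_level, cfg$sort_bin_size,
            cfg$consecutive_bins)
  if (any(is.na(cnts)) || any(cnts <= 0)) {
    stop("count parameters must be positive", call. = FALSE)
  }
  pos <- c(cfg$toward_halfwidth, cfg$timecourse_window, cfg$timecourse_step,
           cfg$spike_bin, cfg$sustained_min_time, cfg$near_eccentricity_max,
           cfg$rate_kernel_sd)
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    stop("window/step parameters must be positive", call. = FALSE)
  }
  if (!is.finite(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1) {
    stop("'alpha' must lie in (0, 1)", call. = FALSE)
  }
  invisible(cfg)
}

#' Read an analysis configuration from a key-value text file
#'
#' The file holds one `key = value` pair per line; blank lines and lines
#' starting with `#` are ignored. Pair-valued keys (the windows) take two
#' comma-separated numbers. Keys absent from the file keep their
#' [analysis_config()] defaults. Unknown keys are an error rather than a
#' warning: a silently ignored typo in a window bound would corrupt every
#' downstream result.
#'
#' @param path path to the configuration file.
#' @return An `analysis_config` object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  args <- list()
  known <- names(formals(analysis_config))
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      stop("malformed config line (expected key = value): ", ln, call. = FALSE)
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% known) stop("unknown config key: ", key, call. = FALSE)
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    if (key == "bonferroni") {
      parsed <- as.logical(parts)
    } else {
      parsed <- suppressWarnings(as.numeric(parts))
    }
    if (any(is.na(parsed)) && key != "rng_seed") {
      stop("cannot parse value for key '", key, "': ", val, call. = FALSE)
    }
    args[[key]] <- parsed
  }
  do.call(analysis_config, args)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
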