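#' Count spikes in a half-open window
#'
#' Windows are half-open `[t0, t1)` throughout the package so that counts over
#' adjacent windows add without double counting.
#'
#' @param times spike times (ms).
#' @param t0,t1 window bounds, `t0 < t1`.
#' @return integer count.
#' @export
count_spikes <- function(times, t0, t1) {
  if (!(t0 < t1)) stop("t0 must be < t1", call. = FALSE)
  sum(times >= t0 & times < t1)
}

#' Trial-averaged firing-rate curve
#'
#' Each trial's spike times are aligned to its own event time, binned at 1 ms
#' and smoothed with a Gaussian kernel (SD `kernel_sd` ms, truncated at four
#' SDs, normalized to unit mass so that spike mass is conserved); rates are
#' averaged across trials and the SEM over trials is attached.
#'
#' @param trains list of numeric spike-time vectors, one per trial (ms).
#' @param align_times numeric, one alignment time per trial (ms).
#' @param window numeric length-2 (ms relative to the alignment event).
#' @param kernel_sd Gaussian kernel SD in ms.
#' @param bin bin width in ms (default 1).
#' @return object of class `rate_curve`: data.frame with `time` (bin centers),
#'   `rate` (spikes/s), `sem`, and attribute `n_trials`.
#' @export
rate_curve <- function(trains, align_times, window, kernel_sd = 10, bin = 1) {
  if (length(trains) == 0L) stop("empty trial set", call. = FALSE)
  if (length(align_times) != length(trains)) {
    stop("need one alignment time per trial", call. = FALSE)
  }
  pad <- ceiling(4 * kernel_sd / bin)
  edges <- seq(window[1] - pad * bin, window[2] + pad * bin, by = bin)
  centers <- edges[-length(edges)] + bin / 2
  kt <- (-pad:pad) * bin
  kern <- exp(-kt^2 / (2 * kernel_sd^2))
  kern <- kern / sum(kern)
  nb <- length(centers)
  rates <- matrix(0, nrow = length(trains), ncol = nb)
  for (i in seq_along(trains)) {
    rel <- trains[[i]] - align_times[i]
    rel <- rel[rel >= edges[1] & rel < edges[length(edges)]]
    cnt <- numeric(nb)
    if (length(rel)) {
      ix <- floor((rel - edges[1]) / bin) + 1L
      tb <- tabulate(ix, nbins = nb)
      cnt <- tb
    }
    sm <- stats::convolve(cnt, rev(kern), type = "open")
    sm <- sm[(pad + 1L):(pad + nb)]
    rates[i, ] <- sm / (bin / 1000)
  }
  keep <- centers >= window[1] & centers < window[2]
  m <- colMeans(rates[, keep, drop = FALSE])
  s <- if (nrow(rates) > 1L) {
    apply(rates[, keep, drop = FALSE], 2, stats::sd) / sqrt(nrow(rates))
  } else {
    rep(NA_real_, sum(keep))
  }
  out <- data.frame(time = centers[keep], rate = m, sem = s)
  attr(out, "n_trials") <- length(trains)
  class(out) <- c("rate_curve", "data.frame")
  out
}

#' Peak of the visual burst
#'
#' Maximum firing rate, and its time, restricted to the visual burst search
#' window (default 30--100 ms after stimulus onset). Ties take the earliest
#' time. Values outside the window never influence the result.
#'
#' @param x a `rate_curve` (time axis relative to stimulus onset), or a
#'   numeric vector of spike times together with `stimulus_onset`.
#' @param cfg an [analysis_config()].
#' @param stimulus_onset ms; required when `x` is a spike-time vector.
#' @return list with `peak_rate` (spikes/s) and `peak_time` (ms after
#'   stimulus onset).
#' @export
measure_visual_burst <- function(x, cfg = analysis_config(),
                                 stimulus_onset = NULL) {
  w <- cfg$visual_burst_window
  if (is.numeric(x) && !inherits(x, "rate_curve")) {
    if (is.null(stimulus_onset)) {
      stop("stimulus_onset required for a spike-time vector", call. = FALSE)
    }
    x <- rate_curve(list(x), stimulus_onset, window = c(w[1] - 20, w[2] + 20),
                    kernel_sd = cfg$rate_kernel_sd)
  }
  sel <- x$time >= w[1] & x$time < w[2]
  if (!any(sel)) {
    stop("visual burst window lies outside the curve support", call. = FALSE)
  }
  r <- x$rate[sel]
  tt <- x$time[sel]
  i <- which.max(r)   # which.max returns the earliest maximum
  list(peak_rate = r[i], peak_time = tt[i])
}

#' Split trials by microsaccade/visual-burst coincidence
#'
#' "No-saccade" trials have no movement overlapping the -100..+200 ms
#' interval around stimulus onset; "with-saccade" trials have a movement
#' starting or ending (half-open interval) inside the visual burst window.
#' Trials matching neither rule belong to neither group.
#'
#' @param trials data.frame with `trial_id`, `stimulus_onset_ms`.
#' @param saccades data.frame of detected movements with `trial_id`,
#'   `onset_ms`, `offset_ms` (absolute trial time).
#' @param cfg an [analysis_config()].
#' @param quiet_window ms around stimulus onset that must be movement-free
#'   for the no-saccade group.
#' @return list with `no_saccade_trials` and `with_saccade_trials` (trial id
#'   vectors).
#' @export
split_by_saccade_coincidence <- function(trials, saccades,
                                         cfg = analysis_config(),
                                         quiet_window = c(-100, 200)) {
  w <- cfg$visual_burst_window
  no_sac <- with_sac <- logical(nrow(trials))
  sac_by_trial <- split(saccades, saccades$trial_id)
  for (i in seq_len(nrow(trials))) {
    tid <- trials$trial_id[i]
    s0 <- trials$stimulus_onset_ms[i]
    sc <- sac_by_trial[[as.character(tid)]]
    if (is.null(sc) || !nrow(sc)) {
      no_sac[i] <- TRUE
      next
    }
    on <- sc$onset_ms - s0
    off <- sc$offset_ms - s0
    overlaps_quiet <- any(off >= quiet_window[1] & on <= quiet_window[2])
    no_sac[i] <- !overlaps_quiet
    with_sac[i] <- any((on >= w[1] & on < w[2]) | (off >= w[1] & off < w[2]))
  }
  list(no_saccade_trials = trials$trial_id[no_sac],
       with_saccade_trials = trials$trial_id[with_sac])
}

#' Compare peak firing rates between two groups
#'
#' Paired or two-sample (pooled-variance) t-test on per-neuron (or per-trial)
#' peak rates.
#'
#' @param groupA,groupB numeric vectors.
#' @param paired logical.
#' @return list with `statistic`, `p`, `df`, `method`.
#' @export
compare_peak_rates <- function(groupA, groupB, paired = TRUE) {
  if (length(groupA) < 2L || length(groupB) < 2L) {
    stop("need at least 2 observations per group", call. = FALSE)
  }
  if (paired && length(groupA) != length(groupB)) {
    stop("paired comparison needs equal-length groups", call. = FALSE)
  }
  if (paired) {
    d <- groupA - groupB
    if (stats::sd(d) == 0) {
      if (all(d == 0)) {
        return(list(statistic = 0, p = 1, df = length(d) - 1L,
                    method = "Paired t-test"))
      }
      stop("zero variance of nonzero paired differences: t undefined",
           call. = FALSE)
    }
    tt <- stats::t.test(groupA, groupB, paired = TRUE)
  } else {
    if (stats::sd(groupA) == 0 && stats::sd(groupB) == 0) {
      stop("zero variance in both groups: t statistic undefined",
           call. = FALSE)
    }
    tt <- stats::t.test(groupA, groupB, var.equal = TRUE)
  }
  list(statistic = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), method = tt$method)
}
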