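#' Intra-saccadic spike count
#'
#' Number of spikes of the concurrently recorded neuron falling in the
#' intra-saccadic window (default 0--20 ms, half-open) after movement onset.
#'
#' @param saccade one detected movement (list/row with `onset_ms`).
#' @param times spike times of the neuron on the same trial (ms).
#' @param cfg an [analysis_config()].
#' @return integer count.
#' @export
intra_saccadic_count <- function(saccade, times, cfg = analysis_config()) {
  w <- cfg$intra_saccadic_window
  count_spikes(times, saccade$onset_ms + w[1], saccade$onset_ms + w[2])
}

#' Select movements by their timing relative to stimulus onset
#'
#' Three selection regimes are used in the analyses:
#' \describe{
#'   \item{`post_stimulus`}{movements soon after stimulus onset. With
#'     `first_only = TRUE` (the regime of the amplitude model) only the first
#'     movement per trial with onset in `window` (default 0--200 ms) is kept;
#'     with `first_only = TRUE` and `window = c(-100, 150)` this is the
#'     amplitude time-course selection.}
#'   \item{`sustained`}{all movements starting more than
#'     `cfg$sustained_min_time` (550) ms after stimulus onset.}
#'   \item{`baseline`}{all movements starting 500--1500 ms before stimulus
#'     onset.}
#' }
#'
#' @param saccades data.frame of detected movements (`trial_id`, `onset_ms`).
#' @param trials data.frame with `trial_id`, `stimulus_onset_ms`.
#' @param cfg an [analysis_config()].
#' @param mode one of `"post_stimulus"`, `"sustained"`, `"baseline"`.
#' @param window ms relative to stimulus onset (post_stimulus mode).
#' @param first_only keep only the first qualifying movement per trial.
#' @return the selected subset of `saccades`, with an added column
#'   `onset_rel_stim_ms`.
#' @export
select_movements <- function(saccades, trials, cfg = analysis_config(),
                             mode = c("post_stimulus", "sustained",
                                      "baseline"),
                             window = c(0, 200), first_only = (mode ==
                               "post_stimulus")) {
  mode <- match.arg(mode)
  stim <- trials$stimulus_onset_ms[match(saccades$trial_id, trials$trial_id)]
  rel <- saccades$onset_ms - stim
  keep <- switch(mode,
    post_stimulus = rel >= window[1] & rel < window[2],
    sustained = rel > cfg$sustained_min_time,
    baseline = rel >= -1500 & rel <= -500)
  out <- saccades[which(keep), , drop = FALSE]
  out$onset_rel_stim_ms <- rel[which(keep)]
  if (isTRUE(first_only) && nrow(out)) {
    out <- out[order(out$trial_id, out$onset_ms), , drop = FALSE]
    out <- out[!duplicated(out$trial_id), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Retain spike-count levels with enough trials
#'
#' Levels with fewer than `cfg$min_trials_per_level` (15) movements, or above
#' `cfg$max_spike_level` (5), are dropped before fitting the amplitude model.
#'
#' @param n_per_level named vector: names are spike-count levels, values are
#'   movement counts.
#' @param cfg an [analysis_config()].
#' @return sorted numeric vector of retained levels.
#' @export
filter_levels <- function(n_per_level, cfg = analysis_config()) {
  lev <- as.numeric(names(n_per_level))
  keep <- n_per_level >= cfg$min_trials_per_level & lev <= cfg$max_spike_level
  sort(lev[keep])
}

#' Linear model of movement amplitude on intra-saccadic spike count
#'
#' Ordinary least squares on movement-level rows (identity-link Gaussian
#' model `amplitude = beta0 + beta1 * count`), after excluding spike-count
#' levels with fewer than 15 movements and counts above five (see
#' [filter_levels()]). Per-level means are summaries only; the fit uses the
#' raw movements.
#'
#' @param counts integer spike counts, one per movement.
#' @param amplitudes movement amplitudes (deg), same length.
#' @param cfg an [analysis_config()].
#' @return object of class `amplitude_fit`: list with `beta0`, `beta1`,
#'   `se0`, `se1`, `t0`, `t1`, `p0`, `p1`, `F` (model-vs-constant), `pF`,
#'   `n`, `sigma`, `n_per_level` (all levels), `levels_used`.
#' @export
fit_amplitude_model <- function(counts, amplitudes, cfg = analysis_config()) {
  stopifnot(length(counts) == length(amplitudes))
  tab <- table(counts)
  n_per_level <- stats::setNames(as.integer(tab), names(tab))
  levels_used <- filter_levels(n_per_level, cfg)
  keep <- counts %in% levels_used
  x <- counts[keep]
  y <- amplitudes[keep]
  if (length(unique(x)) < 2L) {
    stop("fewer than 2 spike-count levels remain after filtering",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  co <- sm$coefficients
  Fst <- unname(sm$fstatistic)
  if (!is.finite(Fst[1]) || sm$sigma < 1e-12 * max(abs(y), 1)) {
    # numerically exact fit: F is 0 for a flat response, infinite otherwise
    Fst[1] <- if (abs(co[2, 1]) < 1e-12) 0 else Inf
  }
  structure(list(
    beta0 = co[1, 1], beta1 = co[2, 1],
    se0 = co[1, 2], se1 = co[2, 2],
    t0 = co[1, 3], t1 = co[2, 3],
    p0 = co[1, 4], p1 = co[2, 4],
    F = Fst[1], pF = stats::pf(Fst[1], Fst[2], Fst[3], lower.tail = FALSE),
    df_residual = fit$df.residual,
    n = length(x), sigma = sm$sigma,
    n_per_level = n_per_level, levels_used = levels_used),
    class = "amplitude_fit")
}

#' @export
print.amplitude_fit <- function(x, ...) {
  cat(sprintf(
    "<amplitude_fit> n = %d\n  intercept %.5f (se %.5f, t %.2f)\n  slope     %.5f (se %.5f, t %.2f)\n  F = %.2f (p = %.3g)\n",
    x$n, x$beta0, x$se0, x$t0, x$beta1, x$se1, x$t1, x$F, x$pF))
  invisible(x)
}

#' 95% confidence interval for the slope of an amplitude fit
#' @param fit an `amplitude_fit`.
#' @param level confidence level.
#' @return numeric length-2.
#' @export
slope_confint <- function(fit, level = 0.95) {
  q <- stats::qt(1 - (1 - level) / 2, fit$df_residual)
  c(fit$beta1 - q * fit$se1, fit$beta1 + q * fit$se1)
}

#' Sliding-eccentricity slope profile
#'
#' Starting at a preferred eccentricity of 1 deg, a 2-deg-wide window is slid
#' in 1-deg steps; at each center the amplitude model is refit on the pooled
#' movements of all neurons whose RF eccentricity falls inside the (closed)
#' window.
#'
#' @param records data.frame with one row per movement: `count`, `amplitude`,
#'   `ecc` (the recorded neuron's RF eccentricity) and `neuron_id`.
#' @param cfg an [analysis_config()].
#' @param centers window centers in deg (default 1 .. ceiling(max ecc)).
#' @return data.frame with `center`, `slope`, `slope_sem`, `n_neurons`,
#'   `n_movements`; entries are `NA` where no neuron falls in the window or
#'   the fit is undefined.
#' @export
eccentricity_slope_profile <- function(records, cfg = analysis_config(),
                                       centers = NULL) {
  if (is.null(centers)) centers <- seq(1, ceiling(max(records$ecc)))
  out <- data.frame(center = centers, slope = NA_real_,
                    slope_sem = NA_real_, n_neurons = 0L, n_movements = 0L)
  for (i in seq_along(centers)) {
    inwin <- records$ecc >= centers[i] - 1 & records$ecc <= centers[i] + 1
    sub <- records[inwin, , drop = FALSE]
    out$n_neurons[i] <- length(unique(sub$neuron_id))
    out$n_movements[i] <- nrow(sub)
    if (!nrow(sub)) next
    f <- tryCatch(fit_amplitude_model(sub$count, sub$amplitude, cfg),
                  error = function(e) NULL)
    if (!is.null(f)) {
      out$slope[i] <- f$beta1
      out$slope_sem[i] <- f$se1
    }
  }
  out
}

#' Spike-count by eccentricity interaction model
#'
#' OLS fit of `amplitude ~ 1 + count + ecc + count:ecc` on movement-level
#' rows pooled across neurons. The interaction coefficient measures how the
#' per-spike amplitude gain changes per degree of neuronal preferred
#' eccentricity.
#'
#' @param records data.frame with `count`, `ecc`, `amplitude`.
#' @return list with `coefficients` (data.frame: term, estimate, se, t, p),
#'   `interaction` (the count:ecc estimate), `interaction_se`, `n`.
#' @export
fit_interaction_model <- function(records) {
  if (nrow(records) < 4L) stop("need at least 4 rows", call. = FALSE)
  fit <- stats::lm(amplitude ~ count * ecc, data = records)
  if (any(is.na(stats::coef(fit)))) {
    stop("rank-deficient design (constant predictor?)", call. = FALSE)
  }
  co <- summary(fit)$coefficients
  cdf <- data.frame(term = rownames(co), estimate = co[, 1], se = co[, 2],
                    t = co[, 3], p = co[, 4], row.names = NULL)
  list(coefficients = cdf,
       interaction = co["count:ecc", 1],
       interaction_se = co["count:ecc", 2],
       n = nrow(records))
}

#' Running-average time course of movement amplitude
#'
#' Mean amplitude of movements whose onsets fall in 50-ms windows stepped by
#' 10 ms across the -100..+150 ms interval around stimulus onset.
#'
#' @param onsets_rel_stim movement onsets in ms relative to stimulus onset.
#' @param amplitudes movement amplitudes (deg).
#' @param cfg an [analysis_config()].
#' @param range ms; interval spanned by the window centers.
#' @return data.frame `time` (window center), `mean_amp`, `sem`, `n`;
#'   windows containing no movement give `NA`.
#' @export
amplitude_timecourse <- function(onsets_rel_stim, amplitudes,
                                 cfg = analysis_config(),
                                 range = c(-100, 150)) {
  if (!length(onsets_rel_stim)) stop("no movements supplied", call. = FALSE)
  half <- cfg$timecourse_window / 2
  centers <- seq(range[1] + half, range[2] - half, by = cfg$timecourse_step)
  out <- data.frame(time = centers, mean_amp = NA_real_, sem = NA_real_,
                    n = 0L)
  for (i in seq_along(centers)) {
    inw <- onsets_rel_stim >= centers[i] - half &
      onsets_rel_stim < centers[i] + half
    n <- sum(inw)
    out$n[i] <- n
    if (n) {
      a <- amplitudes[inw]
      out$mean_amp[i] <- mean(a)
      out$sem[i] <- if (n > 1L) stats::sd(a) / sqrt(n) else NA_real_
    }
  }
  out
}

#' Burst-timing trial sort with consecutive-bin significance
#'
#' Trials are sorted by the time of the visual burst peak relative to
#' movement onset and grouped into consecutive bins of
#' `cfg$sort_bin_size` (30) trials (a trailing incomplete bin is dropped).
#' Each bin is tested against the first (baseline) bin with a two-sample
#' pooled-variance t-test at a Bonferroni-adjusted alpha. The onset of the
#' amplitude modulation is the first bin opening a run of
#' `cfg$consecutive_bins` (3) significant bins; the offset is the first
#' later bin opening a run of 3 non-significant bins.
#'
#' @param burst_rel_onset per-trial burst-peak time minus movement onset (ms).
#' @param amplitudes per-trial movement amplitudes (deg).
#' @param cfg an [analysis_config()].
#' @param welch use Welch instead of pooled-variance t-tests.
#' @return list: `order` (permutation sorting the trials), `bin_means`,
#'   `bin_times` (mean sort key per bin), `significant` (logical per bin,
#'   `NA` for the baseline bin), `start_bin`, `end_bin` (`NA` if no
#'   qualifying run).
#' @export
sort_and_test_timing <- function(burst_rel_onset, amplitudes,
                                 cfg = analysis_config(), welch = FALSE) {
  n <- length(burst_rel_onset)
  bs <- cfg$sort_bin_size
  if (n < 2L * bs) {
    stop("need at least two bins of trials (", 2L * bs, ")", call. = FALSE)
  }
  ord <- order(burst_rel_onset)
  amp <- amplitudes[ord]
  key <- burst_rel_onset[ord]
  nb <- n %/% bs
  idx <- rep(seq_len(nb), each = bs)
  amp <- amp[seq_len(nb * bs)]
  key <- key[seq_len(nb * bs)]
  bins <- split(amp, idx)
  bin_means <- vapply(bins, mean, numeric(1))
  bin_times <- vapply(split(key, idx), mean, numeric(1))
  alpha <- cfg$alpha
  if (cfg$bonferroni) alpha <- alpha / (nb - 1L)
  sig <- rep(NA, nb)
  for (b in 2:nb) {
    tt <- stats::t.test(bins[[b]], bins[[1L]], var.equal = !welch)
    sig[b] <- tt$p.value < alpha
  }
  runs <- function(v, from, want) {
    k <- cfg$consecutive_bins
    for (b in from:(nb - k + 1L)) {
      if (all(v[b:(b + k - 1L)] == want, na.rm = FALSE)) return(b)
    }
    NA_integer_
  }
  start_bin <- if (nb >= 1L + cfg$consecutive_bins) {
    runs(sig, 2L, TRUE)
  } else NA_integer_
  end_bin <- NA_integer_
  if (!is.na(start_bin) && start_bin + 1L <= nb - cfg$consecutive_bins + 1L) {
    end_bin <- runs(sig, start_bin + 1L, FALSE)
  }
  list(order = ord, bin_means = unname(bin_means),
       bin_times = unname(bin_times), significant = sig,
       start_bin = start_bin, end_bin = end_bin)
}

#' Peri-saccadic spike time course by movement-amplitude bin
#'
#' For each movement, spikes of the paired neuron are counted in 5-ms bins
#' over -100..+100 ms around movement onset; movements are grouped into
#' 0.1-deg amplitude bins (0.1--0.8 deg; smaller movements are excluded) and
#' the mean count per (amplitude bin, time bin) is returned.
#'
#' @param saccades data.frame with `onset_ms`, `amplitude_deg` and `trial_id`.
#' @param trains named list mapping trial id to the neuron's spike times on
#'   that trial (ms).
#' @param cfg an [analysis_config()].
#' @param amp_edges amplitude bin edges (deg).
#' @return object of class `spike_timecourse`: list with `mean_count`
#'   (amplitude bins x time bins), `n` per amplitude bin, `counts` (movement
#'   x time-bin matrix), `amp_bin` (per movement), `time_edges`, `amp_edges`.
#' @export
spike_timecourse_by_amplitude <- function(saccades, trains,
                                          cfg = analysis_config(),
                                          amp_edges = seq(0.1, 0.8, by = 0.1)) {
  te <- seq(cfg$spike_bin_range[1], cfg$spike_bin_range[2], by = cfg$spike_bin)
  nt <- length(te) - 1L
  amp_bin <- cut(saccades$amplitude_deg, amp_edges, right = FALSE,
                 labels = FALSE)
  keep <- which(!is.na(amp_bin))
  counts <- matrix(0L, nrow = length(keep), ncol = nt)
  for (j in seq_along(keep)) {
    i <- keep[j]
    sp <- trains[[as.character(saccades$trial_id[i])]]
    if (is.null(sp) || !length(sp)) next
    rel <- sp - saccades$onset_ms[i]
    rel <- rel[rel >= te[1] & rel < te[length(te)]]
    if (length(rel)) {
      counts[j, ] <- tabulate(floor((rel - te[1]) / cfg$spike_bin) + 1L,
                              nbins = nt)
    }
  }
  ab <- amp_bin[keep]
  nbin <- length(amp_edges) - 1L
  mean_count <- matrix(NA_real_, nrow = nbin, ncol = nt)
  nvec <- integer(nbin)
  for (b in seq_len(nbin)) {
    rows <- ab == b
    nvec[b] <- sum(rows)
    if (nvec[b]) mean_count[b, ] <- colMeans(counts[rows, , drop = FALSE])
  }
  structure(list(mean_count = mean_count, n = nvec, counts = counts,
                 amp_bin = ab, time_edges = te, amp_edges = amp_edges),
            class = "spike_timecourse")
}

#' Half-width of the peri-saccadic spike influence window
#'
#' Compares, per 5-ms time bin, the spike counts accompanying enlarged
#' movements (amplitude at or above `enlarged_min`) against those
#' accompanying baseline-sized movements, using two-sample pooled-variance
#' t-tests with Bonferroni correction over time bins. The contiguous run of
#' significantly elevated bins containing the strongest bin defines the
#' influence window; its outermost absolute edge is returned.
#'
#' @param stc a [spike_timecourse_by_amplitude()] result.
#' @param enlarged_min deg; amplitude from which a movement counts as
#'   enlarged (default 0.3, i.e. above the two baseline bins 0.1--0.3 deg).
#' @param alpha nominal level before Bonferroni correction.
#' @return list with `halfwidth_ms`, `significant` (per time bin),
#'   `run` (bin index range), `tstat`.
#' @export
estimate_influence_halfwidth <- function(stc, enlarged_min = 0.3,
                                         alpha = 0.05) {
  lower <- stc$amp_edges[-length(stc$amp_edges)]
  big <- stc$amp_bin %in% which(lower >= enlarged_min)
  small <- stc$amp_bin %in% which(lower < enlarged_min)
  if (!any(big) || !any(small)) {
    stop("need movements in both the enlarged and baseline amplitude ranges",
         call. = FALSE)
  }
  nt <- ncol(stc$counts)
  tstat <- pval <- numeric(nt)
  for (j in seq_len(nt)) {
    tt <- tryCatch(
      stats::t.test(stc$counts[big, j], stc$counts[small, j],
                    var.equal = TRUE, alternative = "greater"),
      error = function(e) NULL)   # both groups constant in this bin
    tstat[j] <- if (is.null(tt)) 0 else unname(tt$statistic)
    pval[j] <- if (is.null(tt)) 1 else tt$p.value
  }
  pval[!is.finite(pval)] <- 1
  sig <- pval < alpha / nt
  sig[is.na(sig)] <- FALSE
  if (!any(sig)) {
    return(list(halfwidth_ms = NA_real_, significant = sig, run = NULL,
                tstat = tstat))
  }
  anchor <- which.max(ifelse(sig, tstat, -Inf))
  lo <- anchor
  while (lo > 1L && sig[lo - 1L]) lo <- lo - 1L
  hi <- anchor
  while (hi < nt && sig[hi + 1L]) hi <- hi + 1L
  hw <- max(abs(stc$time_edges[lo]), abs(stc$time_edges[hi + 1L]))
  list(halfwidth_ms = hw, significant = sig, run = c(lo, hi), tstat = tstat)
}

#' Efferent lag between neural and behavioral time courses
#'
#' Cross-correlates the mean movement-amplitude time course with the
#' (normalized) population firing-rate time course after resampling both onto
#' a common 1-ms grid and mean-subtracting; only full-overlap lags are
#' scored. Positive lags mean behavior follows the neural activity.
#'
#' @param behavior data.frame with `time` (ms) and a value column (`mean_amp`
#'   or `value`).
#' @param rate data.frame with `time` and `rate` (or `value`).
#' @param lags candidate lags in ms (default 0..100).
#' @param grid_step resampling step in ms.
#' @return list with `lag_ms`, `correlation` (at the best lag), `lags`,
#'   `corr` (profile).
#' @export
estimate_efferent_lag <- function(behavior, rate, lags = 0:100,
                                  grid_step = 1) {
  val <- function(df) {
    v <- df[[intersect(c("mean_amp", "rate", "value"), names(df))[1]]]
    ok <- is.finite(v) & is.finite(df$time)
    list(t = df$time[ok], v = v[ok])
  }
  b <- val(behavior); r <- val(rate)
  lo <- max(min(b$t), min(r$t))
  hi <- min(max(b$t), max(r$t))
  if (hi <= lo) stop("curves do not overlap in time", call. = FALSE)
  g <- seq(lo, hi, by = grid_step)
  bv <- stats::approx(b$t, b$v, xout = g)$y
  rv <- stats::approx(r$t, r$v, xout = g)$y
  corr <- vapply(lags, function(L) {
    k <- round(L / grid_step)
    if (k >= length(g) - 2L) return(NA_real_)
    # behavior at time t against rate at time t - L (full overlap)
    bb <- bv[(k + 1L):length(g)]
    rr <- rv[1L:(length(g) - k)]
    if (stats::sd(bb) == 0 || stats::sd(rr) == 0) return(NA_real_)
    stats::cor(bb, rr)
  }, numeric(1))
  i <- which.max(corr)
  list(lag_ms = lags[i], correlation = corr[i], lags = lags, corr = corr)
}
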