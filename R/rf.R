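#' Movement response field on log-polar axes
#'
#' Bins movements by (log radial amplitude, direction) -- the origin of the
#' log axis sits at `ecc_origin` (0.03 deg) -- and stores, per cell, the mean
#' peri-movement firing rate (spikes within +/-`window` ms of movement onset,
#' divided by the window length).
#'
#' @param saccades data.frame with `trial_id`, `amplitude_deg`,
#'   `direction_deg`, `onset_ms`.
#' @param trains named list mapping trial id to spike times (ms).
#' @param window ms; half-width of the peri-movement rate window.
#' @param ecc_origin deg; radial origin of the log axis.
#' @param n_ecc,n_dir grid resolution.
#' @return object of class `movement_rf`: list with `rate` (n_ecc x n_dir
#'   matrix, spikes/s), `n` (movement counts per cell), `u_centers`
#'   (log-eccentricity), `v_centers` (direction, deg), edges, and the
#'   per-movement table `movements` (`u`, `v`, `rate`).
#' @export
build_movement_rf <- function(saccades, trains, window = 15,
                              ecc_origin = 0.03, n_ecc = 8, n_dir = 12) {
  if (!nrow(saccades)) stop("need at least one movement", call. = FALSE)
  amp <- pmax(saccades$amplitude_deg, ecc_origin)
  u <- log(amp / ecc_origin)
  v <- saccades$direction_deg %% 360
  rate <- vapply(seq_len(nrow(saccades)), function(i) {
    sp <- trains[[as.character(saccades$trial_id[i])]]
    if (is.null(sp)) return(0)
    count_spikes(sp, saccades$onset_ms[i] - window,
                 saccades$onset_ms[i] + window) / (2 * window / 1000)
  }, numeric(1))
  u_edges <- seq(0, max(u) + 1e-9, length.out = n_ecc + 1L)
  v_edges <- seq(0, 360, length.out = n_dir + 1L)
  ui <- pmin(pmax(findInterval(u, u_edges, rightmost.closed = TRUE), 1L),
             n_ecc)
  vi <- pmin(findInterval(v, v_edges), n_dir)
  R <- matrix(NA_real_, n_ecc, n_dir)
  N <- matrix(0L, n_ecc, n_dir)
  for (i in seq_along(u)) {
    N[ui[i], vi[i]] <- N[ui[i], vi[i]] + 1L
  }
  for (e in seq_len(n_ecc)) {
    for (d in seq_len(n_dir)) {
      if (N[e, d] > 0L) R[e, d] <- mean(rate[ui == e & vi == d])
    }
  }
  structure(list(
    rate = R, n = N,
    u_centers = (u_edges[-1] + u_edges[-length(u_edges)]) / 2,
    v_centers = (v_edges[-1] + v_edges[-length(v_edges)]) / 2,
    u_edges = u_edges, v_edges = v_edges, ecc_origin = ecc_origin,
    movements = data.frame(u = u, v = v, rate = rate)),
    class = "movement_rf")
}

#' Two-dimensional Gaussian fit of a movement response field
#'
#' Least-squares fit of `rate = baseline + peak * exp(-(u-mu)^2/(2*su^2)
#' - (dv)^2/(2*sv^2))` to the informative cells of a [build_movement_rf()]
#' map, where `dv` is the circular direction difference from the fitted
#' preferred direction (the direction axis is unwrapped around the map peak,
#' so fits straddling 0/360 behave correctly). The baseline is bounded below
#' by zero.
#'
#' @param map a `movement_rf`.
#' @return object of class `rf_gaussian_fit`: list with `mean`
#'   (`u` = log-eccentricity, `direction` deg), `sd` (length 2), `orientation`
#'   (0: axis-aligned), `peak_rate`, `baseline`, `converged`, `degenerate`.
#' @export
fit_rf_gaussian <- function(map) {
  cells <- which(map$n > 0L, arr.ind = TRUE)
  if (nrow(cells) < 6L) stop("need at least 6 informative cells",
                             call. = FALSE)
  u <- map$u_centers[cells[, 1]]
  v <- map$v_centers[cells[, 2]]
  z <- map$rate[cells]
  rng <- max(z) - min(z)
  if (!is.finite(rng) || rng <= 1e-9 || stats::sd(z) < 1e-9) {
    return(structure(list(mean = c(u = NA_real_, direction = NA_real_),
                          sd = c(NA_real_, NA_real_), orientation = 0,
                          peak_rate = mean(z), baseline = mean(z),
                          converged = FALSE, degenerate = TRUE),
                     class = "rf_gaussian_fit"))
  }
  pk <- which.max(z)
  v0 <- v[pk]
  dv <- ((v - v0 + 180) %% 360) - 180      # unwrap around the peak
  df <- data.frame(u = u, dv = dv, z = z)
  start <- list(b = max(min(z), 1e-3), a = rng, mu = u[pk], mv = 0,
                su = max(diff(range(u)) / 4, 0.1), sv = 45)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ b + a * exp(-(u - mu)^2 / (2 * su^2) - (dv - mv)^2 / (2 * sv^2)),
      data = df, start = start,
      lower = c(b = 0, a = 0, mu = min(u), mv = -180, su = 0.02, sv = 2),
      upper = c(b = max(z), a = 3 * max(z), mu = max(u), mv = 180,
                su = 3 * diff(range(u)) + 1, sv = 180),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(mean = c(u = u[pk], direction = v0),
                          sd = c(NA_real_, NA_real_), orientation = 0,
                          peak_rate = max(z), baseline = min(z),
                          converged = FALSE, degenerate = FALSE),
                     class = "rf_gaussian_fit"))
  }
  p <- as.list(stats::coef(fit))
  structure(list(
    mean = c(u = p$mu, direction = (v0 + p$mv) %% 360),
    sd = c(p$su, p$sv), orientation = 0,
    peak_rate = p$b + p$a, baseline = p$b,
    converged = TRUE, degenerate = p$a < 1e-6),
    class = "rf_gaussian_fit")
}

#' Select movements inside the Gaussian ROI
#'
#' Keeps movements whose (log-eccentricity, direction) coordinates lie within
#' `k` standard deviations (Mahalanobis distance, axis-aligned) of the fitted
#' RF center, i.e. the "within 2 s.d. of the Gaussian peak" region of
#' interest used for preferred-movement selection.
#'
#' @param saccades data.frame with `amplitude_deg`, `direction_deg`.
#' @param fit an `rf_gaussian_fit`.
#' @param k SD multiple (default 2).
#' @param ecc_origin deg; must match the map the fit came from.
#' @return the subset of `saccades` inside the ROI.
#' @export
select_roi_movements <- function(saccades, fit, k = 2, ecc_origin = 0.03) {
  if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
  u <- log(pmax(saccades$amplitude_deg, ecc_origin) / ecc_origin)
  dv <- ((saccades$direction_deg - fit$mean[["direction"]] + 180) %% 360) - 180
  d <- sqrt(((u - fit$mean[["u"]]) / fit$sd[1])^2 + (dv / fit$sd[2])^2)
  saccades[d <= k, , drop = FALSE]
}

#' Population average of per-neuron normalized rate curves
#'
#' Each neuron's curve is divided by that neuron's own reference peak (the
#' same divisor across all of that neuron's conditions) before averaging, so
#' the population curve is invariant to per-neuron multiplicative rate
#' scaling.
#'
#' @param curves list of data.frames with `time` and `rate`, one per neuron,
#'   all on the same time grid.
#' @param ref_peaks numeric, one positive reference peak per neuron.
#' @return data.frame `time`, `mean` (dimensionless), `sem`, with attribute
#'   `n_neurons`.
#' @export
population_average <- function(curves, ref_peaks) {
  if (length(curves) != length(ref_peaks)) {
    stop("need one reference peak per neuron", call. = FALSE)
  }
  if (any(!is.finite(ref_peaks) | ref_peaks <= 0)) {
    stop("reference peaks must be positive", call. = FALSE)
  }
  g <- curves[[1]]$time
  norm <- vapply(seq_along(curves), function(i) {
    if (!isTRUE(all.equal(curves[[i]]$time, g))) {
      stop("curves must share one time grid", call. = FALSE)
    }
    curves[[i]]$rate / ref_peaks[i]
  }, numeric(length(g)))
  norm <- matrix(norm, nrow = length(g))
  out <- data.frame(
    time = g,
    mean = rowMeans(norm),
    sem = if (ncol(norm) > 1L) {
      apply(norm, 1, stats::sd) / sqrt(ncol(norm))
    } else NA_real_)
  attr(out, "n_neurons") <- length(curves)
  out
}

#' Paired comparison of motor-burst rates with and without a peripheral burst
#'
#' Wilcoxon signed-rank test (exact for n <= 25 without ties, normal
#' approximation above) on per-neuron paired rate measurements; a rank-sum
#' variant on the paired samples is available because the original wording
#' is ambiguous.
#'
#' @param baseline,coincident paired per-neuron rates.
#' @param method `"signed_rank"` (default) or `"rank_sum"`.
#' @return list with `statistic`, `p`, `n`, `method`, `degenerate` (TRUE when
#'   all paired differences are zero).
#' @export
paired_burst_comparison <- function(baseline, coincident,
                                    method = c("signed_rank", "rank_sum")) {
  method <- match.arg(method)
  n <- length(baseline)
  if (length(coincident) != n) stop("groups must be paired", call. = FALSE)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- coincident - baseline
  if (all(d == 0)) {
    return(list(statistic = NA_real_, p = NA_real_, n = n, method = method,
                degenerate = TRUE))
  }
  wt <- if (method == "signed_rank") {
    suppressWarnings(stats::wilcox.test(coincident, baseline, paired = TRUE,
                                        exact = sum(d != 0) <= 25))
  } else {
    suppressWarnings(stats::wilcox.test(coincident, baseline, paired = FALSE))
  }
  list(statistic = unname(wt$statistic), p = wt$p.value, n = n,
       method = method, degenerate = FALSE)
}

#' Compare amplitudes of burst-coincident vs baseline movements
#'
#' Two-sample pooled-variance t-test; the +/-25 degree stimulus-congruence
#' filter is expected to have been applied upstream (see [is_congruent()]).
#'
#' @param burst_amps amplitudes of movements coincident with the peripheral
#'   visual burst (deg).
#' @param baseline_amps amplitudes of pre-stimulus baseline movements (deg).
#' @return list with `t`, `p`, `df`, `means` (group means), `n` (group sizes).
#' @export
amplitude_group_comparison <- function(burst_amps, baseline_amps) {
  if (!length(burst_amps) || !length(baseline_amps)) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  if (stats::sd(c(burst_amps, baseline_amps)) == 0) {
    stop("degenerate zero-variance input", call. = FALSE)
  }
  tt <- stats::t.test(burst_amps, baseline_amps, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       means = c(burst = mean(burst_amps), baseline = mean(baseline_amps)),
       n = c(length(burst_amps), length(baseline_amps)))
}

#' Stimulus-congruence predicate for movement directions
#'
#' TRUE when the movement direction lies within `halfwidth` degrees
#' (circular, inclusive) of the peripheral stimulus direction; the default
#' 25-degree half-width is the congruence rule used for amplitude
#' comparisons, distinct from the 90-degree toward/opposite rule.
#'
#' @param direction_deg movement direction(s).
#' @param stimulus_direction_deg stimulus direction.
#' @param halfwidth deg (default 25).
#' @return logical vector.
#' @export
is_congruent <- function(direction_deg, stimulus_direction_deg,
                         halfwidth = 25) {
  d <- abs(((direction_deg - stimulus_direction_deg + 180) %% 360) - 180)
  d <= halfwidth
}
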