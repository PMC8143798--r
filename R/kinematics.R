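#' Coerce to an eye trace matrix
#'
#' An eye trace is a matrix with columns `time_ms`, `x_deg`, `y_deg`,
#' uniformly sampled with strictly increasing time.
#'
#' @param x matrix or data.frame.
#' @return validated numeric matrix.
#' @export
as_eye_trace <- function(x) {
  m <- as.matrix(as.data.frame(x)[, c("time_ms", "x_deg", "y_deg")])
  storage.mode(m) <- "double"
  t <- m[, "time_ms"]
  if (nrow(m) < 2L || any(diff(t) <= 0)) {
    stop("eye trace time must be strictly increasing", call. = FALSE)
  }
  dt <- diff(t)
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt)) {
    stop("eye trace must be uniformly sampled", call. = FALSE)
  }
  m
}

# centered moving average with partial windows at the ends
ma_smooth <- function(v, k) {
  if (k <= 1L) return(v)
  n <- length(v)
  s <- as.numeric(stats::filter(v, rep(1 / k, k), sides = 2))
  half <- k %/% 2L
  for (i in seq_len(min(half, n))) {
    s[i] <- mean(v[max(1L, i - half):min(n, i + half)])
    j <- n - i + 1L
    s[j] <- mean(v[max(1L, j - half):min(n, j + half)])
  }
  s
}

# measured horizontal/vertical velocity (deg/s): smoothing + central diff
measure_velocity <- function(v, dt_s, smooth) {
  s <- ma_smooth(v, smooth)
  n <- length(s)
  out <- numeric(n)
  out[2:(n - 1L)] <- (s[3:n] - s[1:(n - 2L)]) / (2 * dt_s)
  out[1L] <- (s[2L] - s[1L]) / dt_s
  out[n] <- (s[n] - s[n - 1L]) / dt_s
  out
}

#' Radial eye velocity
#'
#' Magnitude of the eye velocity vector, computed after light position
#' smoothing (centered moving average, `smooth` samples) and central
#' differencing; the two endpoint samples use one-sided differences.
#'
#' @param trace an eye trace (see [as_eye_trace()]).
#' @param smooth samples of position smoothing (default 5).
#' @return numeric vector, deg/s, same length as the trace, nonnegative.
#' @export
radial_velocity <- function(trace, smooth = 5L) {
  trace <- as_eye_trace(trace)
  if (nrow(trace) < 3L) stop("need at least 3 samples", call. = FALSE)
  dt_s <- (trace[2L, "time_ms"] - trace[1L, "time_ms"]) / 1000
  vx <- measure_velocity(trace[, "x_deg"], dt_s, smooth)
  vy <- measure_velocity(trace[, "y_deg"], dt_s, smooth)
  sqrt(vx^2 + vy^2)
}

#' Saccade detection parameters
#'
#' The detector is a median-based adaptive radial-velocity threshold
#' (Engbert-style): samples whose radial speed exceeds `lambda` times a
#' median-based speed SD form candidate events; events shorter than
#' `min_duration` ms are discarded and events separated by less than
#' `merge_interval` ms are merged. Event onset/offset are then refined either
#' by walking the speed down to a local minimum (`refine = "threshold"`) or by
#' least-squares fitting a smoothing-matched raised-cosine speed template
#' (`refine = "template"`, the default), which localizes onset at sample
#' precision and yields an unbiased peak-velocity estimate.
#'
#' @param lambda threshold multiplier of the median-based speed SD.
#' @param min_duration ms; minimum above-threshold duration.
#' @param merge_interval ms; events closer than this are merged.
#' @param smooth samples of position smoothing before differentiation.
#' @param refine `"template"` or `"threshold"`.
#' @param d_grid ms; candidate saccade durations for the template fit.
#' @param min_amplitude deg; detections below this are dropped.
#' @export
detect_params <- function(lambda = 6, min_duration = 6, merge_interval = 20,
                          smooth = 5L, refine = c("template", "threshold"),
                          d_grid = seq(10, 40, by = 1), min_amplitude = 0) {
  list(lambda = lambda, min_duration = min_duration,
       merge_interval = merge_interval, smooth = as.integer(smooth),
       refine = match.arg(refine), d_grid = d_grid,
       min_amplitude = min_amplitude)
}

# template bank: measured speed of a unit-amplitude raised-cosine saccade of
# duration D samples, under the same smoothing/differencing as the data.
# Entry k has offset `pad` so that T[pad + 1] aligns with the onset sample.
.template_cache <- new.env(parent = emptyenv())

template_bank <- function(d_samp, dt_s, smooth) {
  key <- paste(c(d_samp, signif(dt_s, 10), smooth), collapse = "_")
  hit <- .template_cache[[key]]
  if (!is.null(hit)) return(hit)
  pad <- smooth %/% 2L + 2L
  flat <- pad + smooth + 2L
  bank <- lapply(d_samp, function(D) {
    tau <- 0:D
    pos <- tau / D - sin(2 * pi * tau / D) / (2 * pi)
    x <- c(rep(0, flat), pos, rep(1, flat))
    sp <- abs(measure_velocity(x, dt_s, smooth))
    i_on <- flat + 1L
    sp[(i_on - pad):(i_on + D + pad)]
  })
  .template_cache[[key]] <- bank
  bank
}

refine_template <- function(speed, i0, i1, d_samp, bank, pad) {
  n <- length(speed)
  cand <- seq(i0 - max(d_samp) %/% 2L - 2L, min(i0 + 3L, i1))
  best <- NULL
  best_score <- -Inf
  lo <- max(1L, min(cand) - pad)
  hi <- min(n, max(cand) + max(d_samp) + pad)
  seg <- speed[lo:hi]
  for (k in seq_along(d_samp)) {
    Tk <- bank[[k]]
    LT <- length(Tk)
    starts <- cand - pad - lo + 1L          # template start within seg
    starts <- starts[starts >= 1L & starts + LT - 1L <= length(seg)]
    if (!length(starts)) next
    idx <- outer(starts, 0:(LT - 1L), "+")
    M <- matrix(seg[idx], nrow = length(starts))
    num <- as.numeric(M %*% Tk)
    score <- num^2 / sum(Tk^2)
    j <- which.max(score)
    if (score[j] > best_score) {
      best_score <- score[j]
      best <- list(onset = starts[j] + pad + lo - 1L,
                   D = d_samp[k],
                   amp_scale = num[j] / sum(Tk^2))
    }
  }
  best
}

refine_threshold <- function(speed, i0, i1, theta) {
  n <- length(speed)
  j <- i0
  while (j > 1L && speed[j - 1L] > theta) j <- j - 1L
  while (j > 1L && speed[j - 1L] < speed[j]) j <- j - 1L
  k <- i1
  while (k < n && speed[k + 1L] > theta) k <- k + 1L
  while (k < n && speed[k + 1L] < speed[k]) k <- k + 1L
  list(onset = j, D = k - j, amp_scale = NA_real_)
}

#' Detect (micro)saccades in an eye trace
#'
#' @param trace an eye trace.
#' @param params a [detect_params()] list.
#' @param trial_id optional id stored in the result.
#' @return data.frame with one row per detected movement: `trial_id`,
#'   `onset_ms`, `peak_vel_ms`, `offset_ms`, `amplitude_deg` (Euclidean
#'   onset-to-offset displacement), `peak_vel_deg_s`, `direction_deg`
#'   (0 = rightward, counter-clockwise positive, in `[0, 360)`).
#' @export
detect_saccades <- function(trace, params = detect_params(),
                            trial_id = NA_integer_) {
  trace <- as_eye_trace(trace)
  t <- trace[, "time_ms"]
  n <- length(t)
  dt_ms <- t[2L] - t[1L]
  dt_s <- dt_ms / 1000
  vx <- measure_velocity(trace[, "x_deg"], dt_s, params$smooth)
  vy <- measure_velocity(trace[, "y_deg"], dt_s, params$smooth)
  speed <- sqrt(vx^2 + vy^2)

  # median-based velocity SD, per component (the square of a nonnegative
  # series has the same median as its square root, so the radial speed
  # itself carries no median-based scale information)
  msd <- function(v) sqrt(max(stats::median(v^2) - stats::median(v)^2, 0))
  sigma <- sqrt(msd(vx)^2 + msd(vy)^2)
  thr <- params$lambda * sigma
  above <- speed > thr
  above[is.na(above)] <- FALSE
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= ceiling(params$min_duration / dt_ms)
  ev <- cbind(starts[keep], ends[keep])
  if (!nrow(ev)) return(empty_saccades(trial_id))

  # merge events separated by less than merge_interval
  gap_samp <- params$merge_interval / dt_ms
  merged <- list(ev[1L, ])
  if (nrow(ev) > 1L) {
    for (i in 2:nrow(ev)) {
      last <- merged[[length(merged)]]
      if (ev[i, 1L] - last[2L] < gap_samp) {
        merged[[length(merged)]] <- c(last[1L], ev[i, 2L])
      } else {
        merged[[length(merged) + 1L]] <- ev[i, ]
      }
    }
  }

  d_samp <- unique(pmax(2L, round(params$d_grid / dt_ms)))
  pad <- params$smooth %/% 2L + 2L
  bank <- if (params$refine == "template") {
    template_bank(d_samp, dt_s, params$smooth)
  }

  out <- vector("list", length(merged))
  for (i in seq_along(merged)) {
    i0 <- merged[[i]][1L]; i1 <- merged[[i]][2L]
    ref <- if (params$refine == "template") {
      refine_template(speed, i0, i1, d_samp, bank, pad)
    } else {
      refine_threshold(speed, i0, i1, max(3 * sigma, 0.05 * max(speed[i0:i1])))
    }
    if (is.null(ref)) next
    on <- max(1L, ref$onset)
    off <- min(n, on + ref$D)
    if (off - on < 2L) next
    dx <- trace[off, "x_deg"] - trace[on, "x_deg"]
    dy <- trace[off, "y_deg"] - trace[on, "y_deg"]
    amp <- sqrt(dx^2 + dy^2)
    # direction from short averaged endpoint windows: halves the angular
    # noise of single samples without touching the amplitude definition
    pre <- max(1L, on - 3L):on
    post <- off:min(n, off + 3L)
    ddx <- mean(trace[post, "x_deg"]) - mean(trace[pre, "x_deg"])
    ddy <- mean(trace[post, "y_deg"]) - mean(trace[pre, "y_deg"])
    pk_idx <- on + which.max(speed[on:off]) - 1L
    pk_idx <- min(max(pk_idx, on + 1L), off - 1L)
    pv <- if (is.finite(ref$amp_scale) && ref$amp_scale > 0) {
      2000 * ref$amp_scale / (ref$D * dt_ms)
    } else {
      max(speed[on:off])
    }
    if (amp < params$min_amplitude || pv <= 0) next
    out[[i]] <- data.frame(
      trial_id = trial_id,
      onset_ms = t[on], peak_vel_ms = t[pk_idx], offset_ms = t[off],
      amplitude_deg = amp, peak_vel_deg_s = pv,
      direction_deg = (atan2(ddy, ddx) * 180 / pi) %% 360)
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out) || !nrow(out)) return(empty_saccades(trial_id))
  out <- out[order(out$onset_ms), , drop = FALSE]
  # enforce non-overlap after refinement
  if (nrow(out) > 1L) {
    keep <- c(TRUE, out$onset_ms[-1L] > out$offset_ms[-nrow(out)])
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

empty_saccades <- function(trial_id = NA_integer_) {
  data.frame(trial_id = trial_id[0], onset_ms = numeric(),
             peak_vel_ms = numeric(), offset_ms = numeric(),
             amplitude_deg = numeric(), peak_vel_deg_s = numeric(),
             direction_deg = numeric())
}

#' Radial eye position over a saccade
#'
#' Euclidean distance of each sample from the eye position at movement onset,
#' evaluated over the onset-to-offset interval.
#'
#' @param trace an eye trace.
#' @param saccade one row of a [detect_saccades()] result (or any list with
#'   `onset_ms` and `offset_ms`).
#' @return numeric vector of distances (deg); first value is exactly 0.
#' @export
radial_position <- function(trace, saccade) {
  trace <- as_eye_trace(trace)
  t <- trace[, "time_ms"]
  if (saccade$onset_ms < t[1L] || saccade$offset_ms > t[length(t)]) {
    stop("saccade interval lies outside the trace", call. = FALSE)
  }
  i0 <- which.min(abs(t - saccade$onset_ms))
  i1 <- which.min(abs(t - saccade$offset_ms))
  dx <- trace[i0:i1, "x_deg"] - trace[i0, "x_deg"]
  dy <- trace[i0:i1, "y_deg"] - trace[i0, "y_deg"]
  sqrt(dx^2 + dy^2)
}

#' Classify movement direction relative to an RF direction
#'
#' Movements whose direction lies within `halfwidth` degrees (circular
#' distance, inclusive at the boundary) of the RF direction are `"toward"`;
#' all others are `"opposite"`. The two classes partition every movement.
#'
#' @param direction_deg movement direction(s) in degrees.
#' @param rf_direction RF hotspot direction in `[0, 360)`.
#' @param halfwidth angular half-width of the toward sector (default 90).
#' @return character vector, `"toward"` or `"opposite"`.
#' @export
classify_direction <- function(direction_deg, rf_direction, halfwidth = 90) {
  if (rf_direction < 0 || rf_direction >= 360) {
    stop("rf_direction must lie in [0, 360)", call. = FALSE)
  }
  d <- abs(((direction_deg - rf_direction + 180) %% 360) - 180)
  ifelse(d <= halfwidth, "toward", "opposite")
}
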