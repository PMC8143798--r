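# Independent oracles, coded from textbook formulas, kept free of any
# package internals so they can arbitrate the implementation.

# OLS via the normal equations, with classical standard errors
ols_oracle <- function(X, y) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  res <- y - X %*% beta
  n <- nrow(X); p <- ncol(X)
  s2 <- sum(res^2) / (n - p)
  se <- sqrt(diag(solve(XtX)) * s2)
  tval <- as.numeric(beta) / se
  list(beta = as.numeric(beta), se = se, t = tval,
       p = 2 * stats::pt(-abs(tval), n - p),
       sigma2 = s2, df = n - p)
}

# classical t-tests from closed forms
ttest_oracle <- function(a, b, paired = FALSE) {
  if (paired) {
    d <- a - b
    n <- length(d)
    tval <- mean(d) / (stats::sd(d) / sqrt(n))
    df <- n - 1
  } else {
    na <- length(a); nb <- length(b)
    sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
      (na + nb - 2)
    tval <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  }
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}

# exact two-sided Wilcoxon signed-rank p by exhaustive sign-flip enumeration
# (assumes no zero differences and no ties in |d|)
wilcox_enum_oracle <- function(x, y) {
  d <- x - y
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  p <- 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs))
  list(V = v_obs, p = min(1, p))
}

# noiseless eye trace containing raised-cosine saccades
# saccades: data.frame(onset_ms, amplitude, duration, direction_deg)
make_trace <- function(length_ms, saccades = NULL, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tt <- 0:(length_ms - 1)
  x <- numeric(length_ms)
  y <- numeric(length_ms)
  if (!is.null(saccades)) {
    for (i in seq_len(nrow(saccades))) {
      i0 <- saccades$onset_ms[i] + 1
      D <- saccades$duration[i]
      tau <- 0:D
      shape <- tau / D - sin(2 * pi * tau / D) / (2 * pi)
      prof <- numeric(length_ms)
      prof[i0:(i0 + D)] <- shape
      if (i0 + D < length_ms) prof[(i0 + D + 1):length_ms] <- 1
      th <- saccades$direction_deg[i] * pi / 180
      x <- x + saccades$amplitude[i] * cos(th) * prof
      y <- y + saccades$amplitude[i] * sin(th) * prof
    }
  }
  if (noise_sd > 0) {
    x <- x + rnorm(length_ms, 0, noise_sd)
    y <- y + rnorm(length_ms, 0, noise_sd)
  }
  cbind(time_ms = tt, x_deg = x, y_deg = y)
}
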