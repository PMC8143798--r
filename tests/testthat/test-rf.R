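make_gauss_map <- function(peak = 80, base = 5, mu_u = 1.6, mu_v = 180,
                           su = 0.5, sv = 40, n_ecc = 8, n_dir = 12,
                           noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  u_edges <- seq(0, 4, length.out = n_ecc + 1)
  v_edges <- seq(0, 360, length.out = n_dir + 1)
  uc <- (u_edges[-1] + u_edges[-length(u_edges)]) / 2
  vc <- (v_edges[-1] + v_edges[-length(v_edges)]) / 2
  R <- outer(uc, vc, function(u, v) {
    dv <- ((v - mu_v + 180) %% 360) - 180
    base + peak * exp(-(u - mu_u)^2 / (2 * su^2) - dv^2 / (2 * sv^2))
  })
  if (noise_sd > 0) R <- pmax(R + rnorm(length(R), 0, noise_sd), 0)
  structure(list(rate = R, n = matrix(5L, n_ecc, n_dir),
                 u_centers = uc, v_centers = vc,
                 u_edges = u_edges, v_edges = v_edges, ecc_origin = 0.03,
                 movements = NULL),
            class = "movement_rf")
}

test_that("movement RF maps localize tuned discharge", {
  set.seed(2)
  n <- 400
  dirs <- runif(n, 0, 360)
  sac <- data.frame(trial_id = 1:n, onset_ms = 500,
                    amplitude_deg = exp(runif(n, log(0.05), log(1))),
                    direction_deg = dirs)
  left <- abs(((dirs - 180 + 180) %% 360) - 180) < 45
  trains <- lapply(1:n, function(i) {
    if (left[i]) 500 + runif(12, -14, 14) else numeric(0)
  })
  names(trains) <- 1:n
  map <- build_movement_rf(sac, trains)
  dist180 <- abs(((map$movements$v - 180 + 180) %% 360) - 180)
  expect_gt(mean(map$movements$rate[dist180 < 45]),
            mean(map$movements$rate[dist180 > 135]) + 50)
  # peak cell direction is leftward
  pk <- which(map$rate == max(map$rate, na.rm = TRUE), arr.ind = TRUE)[1, ]
  expect_lt(abs(((map$v_centers[pk[2]] - 180 + 180) %% 360) - 180), 60)

  none <- lapply(1:n, function(i) numeric(0)); names(none) <- 1:n
  map0 <- build_movement_rf(sac, none)
  expect_true(all(map0$rate[map0$n > 0] == 0))
})

test_that("an exactly Gaussian map is recovered to 1e-3 relative error", {
  map <- make_gauss_map()
  fit <- fit_rf_gaussian(map)
  expect_true(fit$converged)
  expect_false(fit$degenerate)
  expect_lt(abs(fit$mean[["u"]] - 1.6) / 1.6, 1e-3)
  expect_lt(abs(fit$mean[["direction"]] - 180) / 180, 1e-3)
  expect_lt(abs(fit$sd[1] - 0.5) / 0.5, 1e-3)
  expect_lt(abs(fit$peak_rate - 85) / 85, 1e-3)

  flat <- make_gauss_map(peak = 0, base = 10)
  expect_true(fit_rf_gaussian(flat)$degenerate)

  # noisy map: center recovered within half a cell
  for (seed in 1:3) {
    noisy <- make_gauss_map(noise_sd = 6, seed = seed)
    fn <- fit_rf_gaussian(noisy)
    expect_true(fn$converged)
    expect_lt(abs(fn$mean[["u"]] - 1.6), 0.25)        # cell width 0.5
    expect_lt(abs(((fn$mean[["direction"]] - 180 + 180) %% 360) - 180), 15)
  }
})

test_that("a Gaussian straddling the 0/360 seam is fit correctly", {
  map <- make_gauss_map(mu_v = 10)
  fit <- fit_rf_gaussian(map)
  d <- abs(((fit$mean[["direction"]] - 10 + 180) %% 360) - 180)
  expect_lt(d, 2)
})

test_that("ROI selection matches the analytic 2-sd Mahalanobis mass", {
  fit <- structure(list(mean = c(u = 1.6, direction = 180), sd = c(0.5, 40),
                        orientation = 0, peak_rate = 80, baseline = 5,
                        converged = TRUE, degenerate = FALSE),
                   class = "rf_gaussian_fit")
  at_mean <- data.frame(amplitude_deg = 0.03 * exp(1.6), direction_deg = 180)
  expect_equal(nrow(select_roi_movements(at_mean, fit)), 1L)
  at_3sd <- data.frame(amplitude_deg = 0.03 * exp(1.6 + 3 * 0.5),
                       direction_deg = 180)
  expect_equal(nrow(select_roi_movements(at_3sd, fit)), 0L)

  set.seed(13)
  n <- 10000
  sim <- data.frame(
    amplitude_deg = 0.03 * exp(rnorm(n, 1.6, 0.5)),
    direction_deg = (rnorm(n, 180, 40)) %% 360)
  frac <- nrow(select_roi_movements(sim, fit)) / n
  expect_lt(abs(frac - pchisq(4, df = 2)), 0.02)
})

test_that("population averaging normalizes per neuron before pooling", {
  g <- data.frame(time = 0:100, rate = sin(0:100 / 15) + 2)
  one <- population_average(list(g), ref_peaks = max(g$rate))
  expect_equal(one$mean, g$rate / max(g$rate))

  two <- population_average(list(g, g), ref_peaks = rep(max(g$rate), 2))
  expect_true(all(two$sem == 0))

  g10 <- g; g10$rate <- g$rate * 10
  mixed <- population_average(list(g, g10),
                              ref_peaks = c(max(g$rate), max(g10$rate)))
  expect_equal(mixed$mean, one$mean)
  expect_error(population_average(list(g), 0), "positive")
})

test_that("the Wilcoxon comparison equals exhaustive sign-flip enumeration", {
  x <- c(1, 2, 3); y <- c(2, 4, 6)
  got <- paired_burst_comparison(x, y)
  want <- wilcox_enum_oracle(y, x)
  expect_equal(got$statistic, want$V)
  expect_equal(got$p, want$p, tolerance = 1e-12)

  set.seed(17)
  for (n in c(5, 8, 10)) {
    for (rep in 1:5) {
      a <- rnorm(n); b <- a + rnorm(n, 0.3)
      got <- paired_burst_comparison(a, b)
      want <- wilcox_enum_oracle(b, a)
      expect_equal(got$statistic, want$V)
      expect_equal(got$p, want$p, tolerance = 1e-12)
    }
  }
  same <- c(4, 4, 5)
  expect_true(paired_burst_comparison(same, same)$degenerate)
  expect_error(paired_burst_comparison(1, 2), "2 pairs")
})

test_that("amplitude group comparisons detect the burst-coincident shift", {
  x <- rnorm(30)
  expect_equal(amplitude_group_comparison(x, x)$t, 0, tolerance = 1e-12)
  expect_error(amplitude_group_comparison(numeric(0), x), "nonempty")
  expect_error(amplitude_group_comparison(rep(1, 5), rep(1, 5)),
               "degenerate")

  set.seed(18)
  hits <- 0
  for (r in 1:200) {
    base <- rnorm(200, 0.12, 0.05)
    burst <- rnorm(200, 0.17, 0.05)
    if (amplitude_group_comparison(burst, base)$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.95)
})

test_that("the 25-degree congruence rule is circular and inclusive", {
  expect_true(is_congruent(20, 0))
  expect_true(is_congruent(350, 10))
  expect_false(is_congruent(40, 0))
  expect_true(is_congruent(25, 0))
})
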