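test_that("intra-saccadic counting matches a linear-scan oracle", {
  s <- list(onset_ms = 250)
  expect_identical(intra_saccadic_count(s, 250 + c(1, 10, 19)), 3L)
  expect_identical(intra_saccadic_count(s, 250 + 25), 0L)
  set.seed(8)
  for (i in 1:15) {
    train <- sort(runif(80, 0, 600))
    on <- runif(1, 50, 500)
    oracle <- 0L
    for (tt in train) if (tt >= on && tt < on + 20) oracle <- oracle + 1L
    expect_identical(intra_saccadic_count(list(onset_ms = on), train), oracle)
  }
})

test_that("movement selection honors the printed time windows", {
  trials <- data.frame(trial_id = 1:4, stimulus_onset_ms = 1000)
  sac <- data.frame(trial_id = c(1, 1, 2, 3, 4),
                    onset_ms = 1000 + c(100, 150, 600, -700, 250),
                    amplitude_deg = 0.15)
  glm_sel <- select_movements(sac, trials, mode = "post_stimulus")
  expect_equal(glm_sel$onset_rel_stim_ms, 100)  # first qualifying per trial
  sus <- select_movements(sac, trials, mode = "sustained")
  expect_equal(sus$onset_rel_stim_ms, 600)
  base <- select_movements(sac, trials, mode = "baseline")
  expect_equal(base$onset_rel_stim_ms, -700)
  tc <- select_movements(sac, trials, mode = "post_stimulus",
                         window = c(-100, 150))
  expect_setequal(tc$onset_rel_stim_ms, 100)    # 150 excluded (half-open)
  expect_error(select_movements(sac, trials, mode = "nonsense"))
})

test_that("level filtering reproduces the trial-count and count>5 rules", {
  cfg <- analysis_config()
  fig4 <- c("0" = 1772, "1" = 383, "2" = 237, "3" = 145, "4" = 113,
            "5" = 78)
  expect_identical(filter_levels(fig4, cfg), as.numeric(0:5))
  expect_identical(filter_levels(c("0" = 30, "1" = 14), cfg), 0)
  many <- c("0" = 20, "1" = 20, "2" = 20, "6" = 50)
  expect_identical(filter_levels(many, cfg), c(0, 1, 2))  # 6 dropped anyway
})

test_that("the amplitude model equals the normal-equations oracle", {
  # exact interpolation
  n <- rep(0:3, each = 20)
  amp <- 0.1 + 0.05 * n
  f <- fit_amplitude_model(n, amp)
  expect_equal(f$beta0, 0.1, tolerance = 1e-12)
  expect_equal(f$beta1, 0.05, tolerance = 1e-12)

  # constant amplitudes
  f0 <- fit_amplitude_model(n, rep(0.15, length(n)))
  expect_equal(f0$beta1, 0, tolerance = 1e-12)
  expect_equal(f0$F, 0, tolerance = 1e-12)

  # random data against the oracle, plus F = t1^2
  set.seed(21)
  for (i in 1:8) {
    x <- sample(0:5, 400, replace = TRUE, prob = c(12, 4, 2, 1, 1, 1))
    y <- 0.14 + 0.066 * x + rnorm(400, 0, 0.05)
    f <- fit_amplitude_model(x, y)
    keep <- x %in% f$levels_used
    o <- ols_oracle(cbind(1, x[keep]), y[keep])
    expect_equal(f$beta0, o$beta[1], tolerance = 1e-10)
    expect_equal(f$beta1, o$beta[2], tolerance = 1e-10)
    expect_equal(f$se1, unname(o$se[2]), tolerance = 1e-10)
    expect_equal(f$p1, unname(o$p[2]), tolerance = 1e-10)
    expect_equal(f$F, f$t1^2, tolerance = 1e-8)
  }
  expect_error(fit_amplitude_model(rep(2, 40), rnorm(40)), "2 spike-count")
})

test_that("excluding the zero-spike level barely moves a well-specified slope", {
  cfg <- sim_config(seed = 33, n_trials = 4000)
  gt <- simulate_movements(cfg)
  tw <- gt[gt$direction_class == "toward", ]
  f_all <- fit_amplitude_model(tw$spike_count, tw$amplitude_deg)
  nz <- tw$spike_count > 0
  f_nz <- fit_amplitude_model(tw$spike_count[nz], tw$amplitude_deg[nz])
  expect_lt(abs(f_all$beta1 - f_nz$beta1), f_nz$se1)
})

test_that("per-level mean amplitude is nondecreasing under a positive gain", {
  gt <- simulate_movements(sim_config(seed = 34, n_trials = 6000))
  tw <- gt[gt$direction_class == "toward" & gt$spike_count <= 5, ]
  mu <- tapply(tw$amplitude_deg, tw$spike_count, mean)
  expect_true(all(diff(mu) > -0.005))
})

test_that("sliding eccentricity windows define slopes only where neurons fall", {
  set.seed(4)
  rec3 <- data.frame(count = sample(0:4, 600, TRUE), ecc = 3,
                     neuron_id = "a")
  rec3$amplitude <- 0.14 + 0.05 * rec3$count + rnorm(600, 0, 0.04)
  prof <- eccentricity_slope_profile(rec3, centers = 1:5)
  expect_true(all(is.na(prof$slope[prof$center %in% c(1, 5)])))
  expect_true(all(!is.na(prof$slope[prof$center %in% 2:4])))

  # declining gain: fitted slopes decline in expectation
  gt <- simulate_movements(fixture_config("ecc_gradient", seed = 44,
                                          n_trials = 12000))
  tw <- gt[gt$direction_class == "toward", ]
  rec <- data.frame(count = tw$spike_count, amplitude = tw$amplitude_deg,
                    ecc = tw$ecc, neuron_id = tw$neuron_id)
  prof2 <- eccentricity_slope_profile(rec)
  ok <- !is.na(prof2$slope)
  expect_lt(stats::coef(lm(prof2$slope[ok] ~ prof2$center[ok]))[2], 0)
  expect_gt(prof2$slope[prof2$center == 2],
            prof2$slope[prof2$center == 9])
})

test_that("the 4-term interaction model matches exact and oracle solutions", {
  # noiseless: amp = a + (g0 + g1 ecc) n recovers g1 exactly
  d <- expand.grid(count = 0:4, ecc = c(1, 3, 5, 8))
  d$amplitude <- 0.12 + (0.09 - 0.008 * d$ecc) * d$count
  fit <- fit_interaction_model(d)
  expect_equal(fit$interaction, -0.008, tolerance = 1e-12)

  set.seed(6)
  d2 <- data.frame(count = sample(0:5, 500, TRUE),
                   ecc = sample(1:10, 500, TRUE))
  d2$amplitude <- 0.13 + 0.07 * d2$count - 0.006 * d2$count * d2$ecc +
    rnorm(500, 0, 0.05)
  fit2 <- fit_interaction_model(d2)
  X <- cbind(1, d2$count, d2$ecc, d2$count * d2$ecc)
  o <- ols_oracle(X, d2$amplitude)
  expect_equal(fit2$interaction, o$beta[4], tolerance = 1e-10)
  expect_equal(fit2$interaction_se, unname(o$se[4]), tolerance = 1e-10)

  d3 <- d2; d3$ecc <- 4
  expect_error(fit_interaction_model(d3), "rank")
})

test_that("amplitude time courses follow window membership", {
  on <- rep(0, 50)
  at <- amplitude_timecourse(on, rep(0.15, 50))
  expect_true(all(abs(at$mean_amp[at$n > 0] - 0.15) < 1e-12))

  set.seed(9)
  on2 <- runif(400, -100, 150)
  amp2 <- ifelse(on2 > 50 & on2 < 100, 0.3, 0.12)
  at2 <- amplitude_timecourse(on2, amp2)
  half <- 25
  for (i in seq_len(nrow(at2))) {
    inw <- on2 >= at2$time[i] - half & on2 < at2$time[i] + half
    if (any(inw)) expect_equal(at2$mean_amp[i], mean(amp2[inw]))
    overlaps <- (at2$time[i] + half) > 50 & (at2$time[i] - half) < 100
    if (!overlaps && any(inw)) expect_lt(at2$mean_amp[i], 0.13)
  }

  single <- amplitude_timecourse(10, 0.2)
  expect_true(all(is.na(single$mean_amp[single$n == 0])))
  expect_true(all(single$mean_amp[single$n > 0] == 0.2))
})

test_that("burst-timing sort finds onset and offset of step modulations", {
  set.seed(12)
  key <- seq_len(390) + rnorm(390, 0, 0.01)   # already sorted order
  amp <- c(rnorm(90, 0.12, 0.01), rnorm(210, 0.30, 0.01),
           rnorm(90, 0.12, 0.01))
  res <- sort_and_test_timing(key, amp)
  expect_equal(res$start_bin, 4L)
  expect_equal(res$end_bin, 11L)
  expect_error(sort_and_test_timing(1:59, rnorm(59)), "two bins")

  # localization within one bin on noisier step data (SNR >= 10)
  for (seed in 1:5) {
    set.seed(100 + seed)
    amp2 <- c(rnorm(120, 0.12, 0.015), rnorm(150, 0.32, 0.015),
              rnorm(120, 0.12, 0.015))
    res2 <- sort_and_test_timing(seq_along(amp2), amp2)
    expect_lte(abs(res2$start_bin - 5L), 1L)
    expect_lte(abs(res2$end_bin - 10L), 1L)
  }
})

test_that("a null burst-timing sort rarely reports an onset", {
  set.seed(14)
  n_rep <- 150
  false_start <- 0
  for (r in seq_len(n_rep)) {
    amp <- rnorm(150, 0.15, 0.03)
    res <- sort_and_test_timing(seq_len(150), amp)
    if (!is.na(res$start_bin)) false_start <- false_start + 1
  }
  expect_lte(false_start / n_rep, 0.05 + 2 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("spike time courses by amplitude bin behave as constructed", {
  # homogeneous Poisson at rate r: every 5-ms bin ~ 0.005 r counts
  set.seed(15)
  r <- 40
  n <- 600
  sac <- data.frame(trial_id = 1:n, onset_ms = 300,
                    amplitude_deg = runif(n, 0.1, 0.8))
  trains <- lapply(1:n, function(i) sort(runif(rpois(1, r * 0.6), 0, 600)))
  names(trains) <- 1:n
  stc <- spike_timecourse_by_amplitude(sac, trains)
  expect_true(all(abs(colMeans(stc$counts) - 0.005 * r) < 0.06))

  # no spikes -> all zeros
  empty <- lapply(1:n, function(i) numeric(0)); names(empty) <- 1:n
  stc0 <- spike_timecourse_by_amplitude(sac, empty)
  expect_true(all(stc0$mean_count[stc0$n > 0, ] == 0))

  # spikes only at onset +/- 10 ms for large movements
  big <- sac$amplitude_deg >= 0.5
  tr2 <- lapply(1:n, function(i) {
    if (big[i]) 300 + runif(8, -10, 10) else numeric(0)
  })
  names(tr2) <- 1:n
  stc2 <- spike_timecourse_by_amplitude(sac, tr2)
  hw <- estimate_influence_halfwidth(stc2, enlarged_min = 0.5)
  expect_equal(hw$halfwidth_ms, 10)
  inner <- stc2$time_edges[-length(stc2$time_edges)] >= -10 &
    stc2$time_edges[-1] <= 10
  big_bins <- which(stc2$amp_edges[-length(stc2$amp_edges)] >= 0.5)
  expect_true(all(stc2$mean_count[big_bins, !inner][stc2$n[big_bins] > 0] == 0))
})

test_that("cross-correlation lag estimation recovers constructed shifts", {
  g <- seq(-100, 150, 1)
  f <- function(t) exp(-(t - 60)^2 / 300)
  same <- estimate_efferent_lag(data.frame(time = g, value = f(g)),
                                data.frame(time = g, value = f(g)))
  expect_equal(same$lag_ms, 0)
  shift <- estimate_efferent_lag(data.frame(time = g, value = f(g - 20)),
                                 data.frame(time = g, value = f(g)))
  expect_equal(shift$lag_ms, 20)
  set.seed(16)
  for (i in 1:5) {
    noisy <- estimate_efferent_lag(
      data.frame(time = seq(-75, 125, 10),
                 value = f(seq(-75, 125, 10) - 20) +
                   rnorm(21, 0, 0.02)),
      data.frame(time = g, value = f(g)))
    expect_lte(abs(noisy$lag_ms - 20), 5)
  }
  expect_error(estimate_efferent_lag(data.frame(time = 1:10, value = 1:10),
                                     data.frame(time = 50:60, value = 1)),
               "overlap")
})

test_that("null-gain sessions give ~95% slope CI coverage", {
  # 500 independent 60-trial blocks; the opposite-direction gain is 0 by
  # construction, so the slope CI should cover 0 at ~the nominal rate
  cfg <- sim_config(seed = 77, n_trials = 30000, trial_length = 900,
                    stimulus_onset = 120, conditions = 40,
                    burst_latency = 40, burst_peak_rate = 120,
                    baseline_rate = 25, sustained_rate = 25,
                    neurons = data.frame(neuron_id = "n1",
                                         cls = "visual_motor",
                                         site = "caudal", rf_ecc_deg = 3,
                                         rf_dir_deg = 0))
  gt <- simulate_movements(cfg)
  block <- (gt$trial_id - 1) %/% 60 + 1
  cfg_small <- analysis_config(min_trials_per_level = 5)
  cover <- logical(0)
  for (b in unique(block)) {
    sub <- gt[block == b & gt$direction_class == "opposite", ]
    f <- tryCatch(
      fit_amplitude_model(sub$spike_count, sub$amplitude_deg, cfg_small),
      error = function(e) NULL)
    if (is.null(f)) next
    ci <- slope_confint(f)
    cover <- c(cover, ci[1] <= 0 && 0 <= ci[2])
  }
  expect_gte(length(cover), 500)
  p_hat <- mean(cover)
  expect_lt(abs(p_hat - 0.95), 3 * sqrt(0.95 * 0.05 / length(cover)))
})
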