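test_that("a fixed seed yields bit-identical sessions", {
  a <- make_fixture("exp1_near", seed = 5, n_trials = 40)
  b <- make_fixture("exp1_near", seed = 5, n_trials = 40)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(a$eye[["1"]], b$eye[["1"]])
  c <- make_fixture("exp1_near", seed = 6, n_trials = 40)
  expect_false(identical(a$spikes, c$spikes))
})

test_that("zero gain leaves toward amplitudes at the configured baseline", {
  gt <- simulate_movements(fixture_config("null_opposite", seed = 8,
                                          n_trials = 3000))
  tw <- gt$amplitude_deg[gt$direction_class == "toward"]
  expect_gt(length(tw), 500)
  expect_lt(abs(mean(tw) - 0.14253), 3 * sd(tw) / sqrt(length(tw)) + 1e-3)
})

test_that("regressing amplitudes on true counts recovers the gain", {
  gt <- simulate_movements(sim_config(seed = 9, n_trials = 6000))
  tw <- gt[gt$direction_class == "toward", ]
  expect_gt(nrow(tw), 800)
  f <- fit_amplitude_model(tw$spike_count, tw$amplitude_deg)
  expect_lt(abs(f$beta1 - 0.066294), 2 * f$se1)
  expect_lt(abs(f$beta0 - 0.14253), 2 * f$se0)
})

test_that("window spike counts are Poisson with the integrated-rate mean", {
  cfg <- sim_config(seed = 10, n_trials = 10000, trial_length = 300,
                    conditions = 80, burst_latency = 35,
                    burst_peak_rate = 350)
  b <- simulate_session(cfg, traces = FALSE)
  w <- c(140, 200)  # spans the burst
  counts <- vapply(split(b$spikes$time_ms, factor(b$spikes$trial_id,
                                                  levels = 1:10000)),
                   function(s) count_spikes(s, w[1], w[2]), integer(1))
  tt <- seq(w[1], w[2], by = 0.01)
  r <- sim_rate_profile(cfg, cfg$neurons[1, ], 80, tt, 120)
  lambda <- sum((r[-1] + r[-length(r)]) / 2) * 0.01 / 1000
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / length(counts)))
  # chi-square GOF against the Poisson pmf, pooling sparse tails
  kmax <- max(counts)
  obs <- tabulate(counts + 1L, nbins = kmax + 1L)
  p <- dpois(0:kmax, lambda)
  p[kmax + 1L] <- p[kmax + 1L] + stats::ppois(kmax, lambda,
                                              lower.tail = FALSE)
  while (length(p) > 2 && length(counts) * p[length(p)] < 5) {
    n2 <- length(p)
    p[n2 - 1L] <- p[n2 - 1L] + p[n2]
    obs[n2 - 1L] <- obs[n2 - 1L] + obs[n2]
    p <- p[-n2]; obs <- obs[-n2]
  }
  gof <- suppressWarnings(stats::chisq.test(obs, p = p))
  expect_gt(gof$p.value, 0.01)
})

test_that("boxcar-mode spikes outside the kernel do not predict amplitude", {
  cfg <- fixture_config("boxcar_influence", seed = 12, n_trials = 1200)
  b <- simulate_session(cfg, traces = FALSE)
  gt <- b$ground_truth
  gt <- gt[gt$direction_class == "toward", ]
  spl <- split(b$spikes$time_ms, b$spikes$trial_id)
  s_out <- vapply(seq_len(nrow(gt)), function(i) {
    st <- spl[[as.character(gt$trial_id[i])]]
    if (is.null(st)) return(0L)
    count_spikes(st, gt$onset_ms[i] + 40, gt$onset_ms[i] + 100)
  }, integer(1))
  # partial correlation of amplitude with outside-kernel counts, given the
  # true in-kernel count, vanishes by construction
  r_amp <- residuals(lm(gt$amplitude_deg ~ gt$spike_count))
  r_out <- residuals(lm(s_out ~ gt$spike_count))
  expect_lt(abs(cor(r_amp, r_out)), 2.6 / sqrt(nrow(gt)))
})

test_that("detection recovers nearly all injected movements of 0.1 deg or more", {
  hits <- 0; total <- 0; err <- numeric(0)
  for (seed in 31:33) {
    b <- make_fixture("exp1_near", seed = seed, n_trials = 160)
    det <- detect_session(b)
    gt <- b$ground_truth
    gt <- gt[gt$amplitude_deg >= 0.1, ]
    for (i in seq_len(nrow(gt))) {
      cand <- det[det$trial_id == gt$trial_id[i] &
                    abs(det$onset_ms - gt$onset_ms[i]) <= 5, ]
      total <- total + 1
      if (nrow(cand)) {
        hits <- hits + 1
        err <- c(err, min(abs(cand$onset_ms - gt$onset_ms[i])))
      }
    }
  }
  expect_gt(total, 120)
  expect_gte(hits / total, 0.98)
  expect_lte(mean(err), 2)
})

test_that("fixtures encode their scenario constraints", {
  near <- fixture_config("exp1_near")
  expect_true(all(near$neurons$rf_ecc_deg >= 1 &
                    near$neurons$rf_ecc_deg <= 4.5))
  expect_identical(near$conditions, c(20, 40, 80))
  sus <- fixture_config("exp2_sustained")
  expect_gte(sus$trial_length, 1300)
  expect_gt(sus$sustained_rate, 0)
  far <- fixture_config("exp1_far")
  expect_true(all(far$neurons$rf_ecc_deg > 4.5))
  expect_error(fixture_config("no_such_fixture"), "unknown fixture")
  expect_error(sim_config(baseline_rate = -1), "nonnegative")
  expect_error(sim_config(gain_vs_ecc = c(0.01, -0.01),
                          neurons = data.frame(
                            neuron_id = "x", cls = "visual_motor",
                            site = "caudal", rf_ecc_deg = 5,
                            rf_dir_deg = 0)),
               "negative")
})
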