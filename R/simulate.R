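circ_dist <- function(a, b) abs(((a - b + 180) %% 360) - 180)

#' Generative configuration for synthetic sessions
#'
#' Describes one synthetic recording session: stimulus-locked visual bursts
#' whose latency and peak rate depend on stimulus condition, optional
#' sustained discharge while the stimulus stays on, a refractory renewal
#' process of microsaccades (~700 ms mean inter-movement interval), and a
#' linear amplitude-coupling rule: each movement's amplitude is
#' `base + beta1_eff * S + noise`, where `S` is the neuron's spike count in
#' the influence window. In `count_window` mode the window is the 0--20 ms
#' intra-saccadic interval; in `boxcar_kernel` mode it is
#' `[onset - delay - h, onset - delay + h)`, i.e. spikes lead the behavioral
#' expression by the efferent delay. The toward-direction gain can decline
#' linearly with neuronal preferred eccentricity via `gain_vs_ecc`.
#'
#' @param seed master seed; separate streams for events, spikes, amplitudes
#'   and eye noise are derived from it so that each generative component is
#'   individually reproducible.
#' @param n_trials total trials (split in blocks over the neurons).
#' @param trial_length ms.
#' @param stimulus_onset ms (scalar, or length-2 range sampled uniformly).
#' @param conditions vector of condition values (e.g. contrasts 20/40/80).
#' @param burst_latency,burst_peak_rate per-condition burst latency (ms) and
#'   peak rate (spikes/s).
#' @param burst_shape gamma-pulse shape `k` and mode (ms after latency).
#' @param baseline_rate,sustained_rate spikes/s; the sustained plateau is
#'   active from `sustained_onset` ms after stimulus onset to trial end.
#' @param sustained_onset ms.
#' @param isi_refractory,isi_shape,isi_mean inter-movement interval =
#'   refractory + gamma(shape, mean) (ms).
#' @param baseline_amp_toward,baseline_amp_opposite deg.
#' @param amp_noise_sd,amp_floor deg.
#' @param beta1_toward,beta1_opposite deg/spike.
#' @param gain_vs_ecc optional `c(g0, g1)`: toward gain `g0 + g1 * ecc`.
#' @param influence_mode `"count_window"` or `"boxcar_kernel"`.
#' @param influence_window ms, count_window mode.
#' @param influence_halfwidth ms, boxcar mode.
#' @param efferent_delay ms, boxcar mode.
#' @param neurons data.frame (`neuron_id`, `cls`, `site`, `rf_ecc_deg`,
#'   `rf_dir_deg`).
#' @param motor_peak_rate spikes/s; movement-burst peak of rostral neurons.
#' @param motor_tuning_sd c(log-ecc sd, direction sd deg) of rostral tuning.
#' @param dur_min,dur_coef,dur_exp saccade duration model
#'   `max(dur_min, dur_coef * A^dur_exp)` ms.
#' @param eye_noise_sd deg; white measurement noise on the traces.
#' @param sampling_rate Hz.
#' @param session_id character.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_trials = 600L,
                       trial_length = 400,
                       stimulus_onset = 120,
                       conditions = c(20, 40, 80),
                       burst_latency = c(45, 40, 35),
                       burst_peak_rate = c(150, 250, 350),
                       burst_shape = c(k = 3, mode = 15),
                       baseline_rate = 10,
                       sustained_rate = 20,
                       sustained_onset = 120,
                       isi_refractory = 100,
                       isi_shape = 2,
                       isi_mean = 600,
                       baseline_amp_toward = 0.14253,
                       baseline_amp_opposite = 0.1185,
                       amp_noise_sd = 0.05,
                       amp_floor = 0.04,
                       beta1_toward = 0.066294,
                       beta1_opposite = 0,
                       gain_vs_ecc = NULL,
                       influence_mode = c("count_window", "boxcar_kernel"),
                       influence_window = c(0, 20),
                       influence_halfwidth = 30,
                       efferent_delay = 20,
                       neurons = data.frame(
                         neuron_id = "n1", cls = "visual_motor",
                         site = "caudal", rf_ecc_deg = 3, rf_dir_deg = 0),
                       motor_peak_rate = 150,
                       motor_tuning_sd = c(0.6, 40),
                       dur_min = 15, dur_coef = 20, dur_exp = 0.4,
                       eye_noise_sd = 0.002,
                       sampling_rate = 1000,
                       session_id = "sim") {
  cfg <- as.list(environment())
  cfg$influence_mode <- match.arg(influence_mode)
  cfg$seed <- as.integer(seed)
  cfg$n_trials <- as.integer(n_trials)
  rates <- c(cfg$baseline_rate, cfg$sustained_rate, cfg$burst_peak_rate,
             cfg$motor_peak_rate)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("all rates must be nonnegative", call. = FALSE)
  }
  if (length(cfg$burst_latency) != length(cfg$conditions) ||
      length(cfg$burst_peak_rate) != length(cfg$conditions)) {
    stop("burst_latency and burst_peak_rate need one value per condition",
         call. = FALSE)
  }
  g <- sim_gain(cfg, cfg$neurons$rf_ecc_deg)
  if (any(g < 0)) {
    stop("toward gain is negative at a configured eccentricity",
         call. = FALSE)
  }
  if (cfg$amp_noise_sd < 0 || cfg$eye_noise_sd < 0) {
    stop("noise SDs must be nonnegative", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

# toward-direction per-spike gain at eccentricity ecc
sim_gain <- function(cfg, ecc) {
  if (!is.null(cfg$gain_vs_ecc)) {
    cfg$gain_vs_ecc[1] + cfg$gain_vs_ecc[2] * ecc
  } else {
    rep(cfg$beta1_toward, length(ecc))
  }
}

#' Configured firing-rate profile of a simulated neuron
#'
#' Deterministic intensity (spikes/s) of the inhomogeneous Poisson process
#' used by [simulate_session()], evaluated at `times` (ms from trial start).
#' Visual neurons: baseline + condition-dependent gamma burst pulse +
#' sustained plateau. Rostral motor neurons: baseline + movement-tuned
#' Gaussian pulses around each event in `events`.
#'
#' @param cfg a [sim_config()].
#' @param neuron one row of `cfg$neurons`.
#' @param condition_value condition of the trial.
#' @param times ms.
#' @param stim_onset ms.
#' @param events optional data.frame (`onset_ms`, `direction_deg`,
#'   `amplitude_deg`) for motor neurons.
#' @return numeric vector of rates.
#' @export
sim_rate_profile <- function(cfg, neuron, condition_value, times, stim_onset,
                             events = NULL) {
  r <- rep(cfg$baseline_rate, length(times))
  if (neuron$cls %in% c("visual", "visual_motor")) {
    ci <- match(condition_value, cfg$conditions)
    lat <- cfg$burst_latency[ci]
    pk <- cfg$burst_peak_rate[ci]
    k <- cfg$burst_shape[["k"]]
    m <- cfg$burst_shape[["mode"]]
    tau <- times - stim_onset - lat
    up <- tau > 0
    r[up] <- r[up] + pk * (tau[up] / m)^(k - 1) * exp((k - 1) * (1 - tau[up] / m))
    sus <- times >= stim_onset + cfg$sustained_onset
    r[sus] <- r[sus] + cfg$sustained_rate
  } else if (neuron$cls == "rostral_motor") {
    if (!is.null(events) && nrow(events)) {
      for (i in seq_len(nrow(events))) {
        u <- log(pmax(events$amplitude_deg[i], 0.03) / 0.03)
        u0 <- log(pmax(neuron$rf_ecc_deg, 0.03) / 0.03)
        tune <- exp(-(u - u0)^2 / (2 * cfg$motor_tuning_sd[1]^2) -
                      circ_dist(events$direction_deg[i],
                                neuron$rf_dir_deg)^2 /
                      (2 * cfg$motor_tuning_sd[2]^2))
        dtm <- times - events$onset_ms[i] - 5
        r <- r + cfg$motor_peak_rate * tune * exp(-dtm^2 / (2 * 8^2))
      }
    }
  }
  r
}

sim_max_rate <- function(cfg, neuron) {
  if (neuron$cls == "rostral_motor") {
    cfg$baseline_rate + cfg$motor_peak_rate + 1
  } else {
    cfg$baseline_rate + max(cfg$burst_peak_rate) + cfg$sustained_rate + 1
  }
}

# renewal microsaccade onsets on the 1-ms grid
sim_event_times <- function(cfg) {
  mean_isi <- cfg$isi_refractory + cfg$isi_mean
  t <- stats::runif(1, 0, mean_isi)
  out <- numeric(0)
  while (t < cfg$trial_length) {
    out <- c(out, t)
    t <- t + cfg$isi_refractory +
      stats::rgamma(1, shape = cfg$isi_shape,
                    scale = cfg$isi_mean / cfg$isi_shape)
  }
  out <- round(out)
  out[out >= 40 & out <= cfg$trial_length - 60]
}

#' Simulate a complete session
#'
#' Generates a [session_bundle] whose statistical structure matches the
#' assumptions of the analysis pipeline: per trial, a stimulus onset, an
#' inhomogeneous-Poisson spike train of the trial's neuron, renewal-process
#' microsaccades whose amplitudes follow the configured linear
#' spike-coupling rule, and (optionally) continuous 1 kHz eye traces built
#' from raised-cosine radial-velocity waveforms plus white fixational noise.
#' The returned bundle carries a `ground_truth` data.frame recording every
#' movement's true onset, direction, spike count in the influence window,
#' effective gain and amplitude.
#'
#' Four RNG streams (events, spikes, amplitudes, eye noise) are derived from
#' `cfg$seed`, so e.g. changing only the noise stream leaves the events
#' identical. A fixed seed yields bit-identical output.
#'
#' @param cfg a [sim_config()].
#' @param traces generate eye traces (set `FALSE` for a fast movement-level
#'   sample when only ground truth is needed).
#' @return a `session_bundle` (with `ground_truth`).
#' @export
simulate_session <- function(cfg, traces = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_trials
  nneur <- nrow(cfg$neurons)
  neuron_ix <- rep(seq_len(nneur), each = ceiling(n / nneur))[seq_len(n)]
  cond <- cfg$conditions[(seq_len(n) - 1L) %% length(cfg$conditions) + 1L]
  stim <- if (length(cfg$stimulus_onset) == 2L) {
    NA_real_  # sampled in the event stream below
  } else rep(cfg$stimulus_onset, n)

  ## stream 1: stimulus times, movement times, directions
  set.seed(cfg$seed + 1L)
  if (length(cfg$stimulus_onset) == 2L) {
    stim <- round(stats::runif(n, cfg$stimulus_onset[1],
                               cfg$stimulus_onset[2]))
  }
  ev <- vector("list", n)
  for (i in seq_len(n)) {
    on <- sim_event_times(cfg)
    if (length(on)) {
      ev[[i]] <- data.frame(trial_id = i, onset_ms = on,
                            direction_deg = stats::runif(length(on), 0, 360))
    }
  }
  events <- do.call(rbind, ev[!vapply(ev, is.null, logical(1))])

  ## stream 2: spike trains of the visual/visual-motor neurons
  set.seed(cfg$seed + 2L)
  is_motor <- cfg$neurons$cls == "rostral_motor"
  spikes <- vector("list", n)
  for (i in seq_len(n)) {
    if (is_motor[neuron_ix[i]]) next
    nr <- cfg$neurons[neuron_ix[i], , drop = FALSE]
    rmax <- sim_max_rate(cfg, nr)
    ncand <- stats::rpois(1, rmax * cfg$trial_length / 1000)
    if (ncand == 0L) next
    tt <- sort(stats::runif(ncand, 0, cfg$trial_length))
    r <- sim_rate_profile(cfg, nr, cond[i], tt, stim[i])
    acc <- stats::runif(ncand) < r / rmax
    if (any(acc)) {
      spikes[[i]] <- data.frame(trial_id = i, neuron_id = nr$neuron_id,
                                time_ms = tt[acc])
    }
  }
  spk <- do.call(rbind, spikes[!vapply(spikes, is.null, logical(1))])
  if (is.null(spk)) {
    spk <- data.frame(trial_id = integer(), neuron_id = character(),
                      time_ms = numeric())
  }

  ## stream 3: movement amplitudes from the coupling rule. Trials recorded
  ## with a rostral motor neuron get no visual-spike coupling (gain 0): the
  ## coupling models spatially dissociated caudal activity, not the movement
  ## burst itself.
  set.seed(cfg$seed + 3L)
  gt <- NULL
  if (!is.null(events) && nrow(events)) {
    ne <- nrow(events)
    nr <- cfg$neurons[neuron_ix[events$trial_id], , drop = FALSE]
    w <- if (cfg$influence_mode == "count_window") {
      cbind(events$onset_ms + cfg$influence_window[1],
            events$onset_ms + cfg$influence_window[2])
    } else {
      cbind(events$onset_ms - cfg$efferent_delay - cfg$influence_halfwidth,
            events$onset_ms - cfg$efferent_delay + cfg$influence_halfwidth)
    }
    spl <- split(spk$time_ms, spk$trial_id)
    S <- integer(ne)
    for (j in seq_len(ne)) {
      st <- spl[[as.character(events$trial_id[j])]]
      if (!is.null(st)) S[j] <- sum(st >= w[j, 1] & st < w[j, 2])
    }
    toward <- circ_dist(events$direction_deg, nr$rf_dir_deg) <= 90
    gain <- ifelse(toward, sim_gain(cfg, nr$rf_ecc_deg), cfg$beta1_opposite)
    gain[nr$cls == "rostral_motor"] <- 0
    base <- ifelse(toward, cfg$baseline_amp_toward, cfg$baseline_amp_opposite)
    amp <- pmax(base + gain * S + stats::rnorm(ne, 0, cfg$amp_noise_sd),
                cfg$amp_floor)
    dur <- pmax(cfg$dur_min, cfg$dur_coef * amp^cfg$dur_exp)
    dur <- round(dur)
    ok <- events$onset_ms + dur + 25 <= cfg$trial_length
    gt <- data.frame(
      trial_id = events$trial_id,
      neuron_id = nr$neuron_id,
      condition_value = cond[events$trial_id],
      stimulus_onset_ms = stim[events$trial_id],
      onset_ms = events$onset_ms,
      direction_deg = events$direction_deg,
      direction_class = ifelse(toward, "toward", "opposite"),
      ecc = nr$rf_ecc_deg,
      spike_count = S,
      beta1_eff = gain,
      base_amp = base,
      amplitude_deg = amp,
      duration_ms = dur,
      peak_vel_deg_s = 2000 * amp / dur)[ok, , drop = FALSE]
    rownames(gt) <- NULL
  }

  ## stream 5: movement-tuned spike trains of rostral motor neurons (their
  ## rate pulses depend on the movements just drawn)
  if (any(is_motor) && !is.null(gt) && nrow(gt)) {
    set.seed(cfg$seed + 5L)
    gt_by_trial <- split(gt, gt$trial_id)
    mspk <- vector("list", n)
    for (i in seq_len(n)) {
      if (!is_motor[neuron_ix[i]]) next
      nr <- cfg$neurons[neuron_ix[i], , drop = FALSE]
      rmax <- sim_max_rate(cfg, nr)
      ncand <- stats::rpois(1, rmax * cfg$trial_length / 1000)
      if (ncand == 0L) next
      tt <- sort(stats::runif(ncand, 0, cfg$trial_length))
      r <- sim_rate_profile(cfg, nr, cond[i], tt, stim[i],
                            events = gt_by_trial[[as.character(i)]])
      acc <- stats::runif(ncand) < r / rmax
      if (any(acc)) {
        mspk[[i]] <- data.frame(trial_id = i, neuron_id = nr$neuron_id,
                                time_ms = tt[acc])
      }
    }
    mspk <- do.call(rbind, mspk[!vapply(mspk, is.null, logical(1))])
    if (!is.null(mspk)) spk <- rbind(spk, mspk)
  }

  ## stream 4: eye traces
  eye <- NULL
  if (traces) {
    set.seed(cfg$seed + 4L)
    dt <- 1000 / cfg$sampling_rate
    tgrid <- seq(0, cfg$trial_length - dt, by = dt)
    ns <- length(tgrid)
    eye <- vector("list", n)
    gts <- if (!is.null(gt)) split(gt, gt$trial_id)
    for (i in seq_len(n)) {
      x <- numeric(ns)
      y <- numeric(ns)
      gti <- gts[[as.character(i)]]
      if (!is.null(gti)) {
        for (j in seq_len(nrow(gti))) {
          i0 <- round(gti$onset_ms[j] / dt) + 1L
          D <- round(gti$duration_ms[j] / dt)
          i1 <- min(i0 + D, ns)
          tau <- seq_len(i1 - i0 + 1L) - 1L
          shape <- tau / D - sin(2 * pi * tau / D) / (2 * pi)
          prof <- numeric(ns)
          prof[i0:i1] <- shape
          if (i1 < ns) prof[(i1 + 1L):ns] <- shape[length(shape)]
          th <- gti$direction_deg[j] * pi / 180
          a <- gti$amplitude_deg[j]
          x <- x + a * cos(th) * prof
          y <- y + a * sin(th) * prof
        }
      }
      if (cfg$eye_noise_sd > 0) {
        x <- x + stats::rnorm(ns, 0, cfg$eye_noise_sd)
        y <- y + stats::rnorm(ns, 0, cfg$eye_noise_sd)
      }
      eye[[as.character(i)]] <- cbind(time_ms = tgrid, x_deg = x, y_deg = y)
    }
  } else {
    # minimal flat traces keep the bundle valid without the synthesis cost
    eye <- lapply(stats::setNames(seq_len(n), seq_len(n)), function(i) {
      cbind(time_ms = c(0, 1), x_deg = c(0, 0), y_deg = c(0, 0))
    })
  }

  trials <- data.frame(trial_id = seq_len(n),
                       stimulus_onset_ms = stim,
                       condition = "condition",
                       condition_value = cond,
                       neuron_id = cfg$neurons$neuron_id[neuron_ix])
  session_bundle(cfg$session_id, cfg$sampling_rate, trials, cfg$neurons,
                 spk, eye, ground_truth = gt)
}

#' Movement-level sample without eye traces
#'
#' Runs the generator's event, spike and amplitude streams only, returning
#' the ground-truth movement table. Used for property checks (CI coverage,
#' Poisson goodness of fit) where trace synthesis and detection are not under
#' test.
#'
#' @param cfg a [sim_config()].
#' @return data.frame of movements (the bundle's `ground_truth`).
#' @export
simulate_movements <- function(cfg) {
  simulate_session(cfg, traces = FALSE)$ground_truth
}

#' Named fixture configurations
#'
#' Deterministic generative configurations matching the study scenarios:
#' \describe{
#'   \item{exp1_near}{near-eccentricity neurons (1--4.5 deg), contrast
#'     conditions 20/40/80, towards gain/intercept set to the printed
#'     experiment-1 towards fit.}
#'   \item{exp1_far}{far neurons (>4.5 deg) with the far-neuron gain.}
#'   \item{ecc_gradient}{neurons spanning 1--10 deg with linearly declining
#'     gain (interaction rate -0.0080709 deg/spike per deg).}
#'   \item{exp2_sustained}{long trials with sustained discharge; gain set to
#'     the sustained-analysis slope 0.0126 deg/spike.}
#'   \item{exp3_dual_site}{one caudal visual-motor and one rostral motor
#'     neuron with long pre-stimulus fixation.}
#'   \item{null_opposite}{zero gain in both directions (null model).}
#'   \item{step_timing}{single near neuron, for the burst-timing sort.}
#'   \item{boxcar_influence}{stationary discharge with a boxcar influence
#'     kernel of +/-30 ms and no efferent delay.}
#'   \item{efferent_lag}{burst-driven coupling through a +/-30 ms boxcar
#'     kernel expressed 20 ms later in behavior.}
#' }
#'
#' @param name fixture name.
#' @param seed master seed.
#' @param n_trials override the fixture's default trial count.
#' @return a `sim_config`.
#' @export
fixture_config <- function(name, seed = 1L, n_trials = NULL) {
  near_neurons <- data.frame(
    neuron_id = paste0("near", 1:6),
    cls = rep(c("visual", "visual_motor"), 3),
    site = "caudal",
    rf_ecc_deg = c(1.5, 2.2, 2.8, 3.3, 3.9, 4.4),
    rf_dir_deg = c(0, 60, 120, 180, 240, 300))
  cfg <- switch(name,
    exp1_near = sim_config(
      seed = seed, n_trials = 1200L, neurons = near_neurons,
      session_id = "exp1_near"),
    exp1_far = sim_config(
      seed = seed, n_trials = 1200L,
      neurons = data.frame(
        neuron_id = paste0("far", 1:4), cls = "visual_motor", site = "caudal",
        rf_ecc_deg = c(6, 7.5, 9, 10), rf_dir_deg = c(0, 90, 180, 270)),
      beta1_toward = 0.0098876, baseline_amp_toward = 0.12368,
      session_id = "exp1_far"),
    ecc_gradient = sim_config(
      seed = seed, n_trials = 1200L,
      neurons = data.frame(
        neuron_id = paste0("e", 1:10), cls = "visual_motor", site = "caudal",
        rf_ecc_deg = 1:10, rf_dir_deg = seq(0, 324, by = 36)),
      gain_vs_ecc = c(0.0885, -0.0080709),
      session_id = "ecc_gradient"),
    exp2_sustained = sim_config(
      seed = seed, n_trials = 400L, trial_length = 1400, stimulus_onset = 100,
      conditions = c(0.56, 2.2, 4.4), burst_latency = c(38, 42, 50),
      burst_peak_rate = c(300, 250, 150), sustained_rate = 25,
      beta1_toward = 0.0126, baseline_amp_toward = 0.1098,
      baseline_amp_opposite = 0.1169,
      neurons = data.frame(
        neuron_id = paste0("s", 1:4), cls = c("visual", "visual_motor",
                                              "visual", "visual_motor"),
        site = "caudal", rf_ecc_deg = c(2, 3, 4, 4.5),
        rf_dir_deg = c(0, 90, 180, 270)),
      session_id = "exp2_sustained"),
    exp3_dual_site = sim_config(
      seed = seed, n_trials = 300L, trial_length = 2000,
      stimulus_onset = 1700, conditions = 100, burst_latency = 40,
      burst_peak_rate = 300, sustained_rate = 0,
      neurons = data.frame(
        neuron_id = c("caudal1", "rostral1"),
        cls = c("visual_motor", "rostral_motor"),
        site = c("caudal", "rostral"),
        rf_ecc_deg = c(6, 0.15), rf_dir_deg = c(0, 180)),
      session_id = "exp3_dual_site"),
    null_opposite = sim_config(
      seed = seed, n_trials = 600L, neurons = near_neurons,
      beta1_toward = 0, beta1_opposite = 0, session_id = "null_opposite"),
    step_timing = sim_config(
      seed = seed, n_trials = 2000L,
      neurons = near_neurons[3, , drop = FALSE],
      session_id = "step_timing"),
    boxcar_influence = sim_config(
      seed = seed, n_trials = 800L, trial_length = 1000, stimulus_onset = 100,
      conditions = 100, burst_latency = 40, burst_peak_rate = 0,
      baseline_rate = 40, sustained_rate = 0,
      influence_mode = "boxcar_kernel", influence_halfwidth = 30,
      efferent_delay = 0,
      neurons = data.frame(neuron_id = "b1", cls = "visual_motor",
                           site = "caudal", rf_ecc_deg = 3, rf_dir_deg = 0),
      session_id = "boxcar_influence"),
    efferent_lag = sim_config(
      seed = seed, n_trials = 1500L, trial_length = 500,
      stimulus_onset = 150, neurons = near_neurons,
      influence_mode = "boxcar_kernel", influence_halfwidth = 30,
      efferent_delay = 20, session_id = "efferent_lag"),
    stop("unknown fixture name: ", name, call. = FALSE))
  if (!is.null(n_trials)) cfg$n_trials <- as.integer(n_trials)
  cfg
}

#' Simulate a named fixture session
#'
#' @inheritParams fixture_config
#' @param traces generate eye traces.
#' @return a `session_bundle` with ground truth.
#' @export
make_fixture <- function(name, seed = 1L, n_trials = NULL, traces = TRUE) {
  simulate_session(fixture_config(name, seed, n_trials), traces = traces)
}
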