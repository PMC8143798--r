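#' Detect microsaccades in every trial of a session
#'
#' @param bundle a `session_bundle`.
#' @param params a [detect_params()] list.
#' @return data.frame of detected movements across trials (see
#'   [detect_saccades()]).
#' @export
detect_session <- function(bundle, params = detect_params()) {
  out <- vector("list", nrow(bundle$trials))
  for (i in seq_len(nrow(bundle$trials))) {
    tid <- bundle$trials$trial_id[i]
    out[[i]] <- detect_saccades(bundle$eye[[as.character(tid)]], params,
                                trial_id = tid)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Movement-level records for the amplitude analyses
#'
#' Runs the full measurement chain on a session: saccade detection on every
#' trial, movement selection by timing relative to stimulus onset,
#' toward/opposite classification against the trial's recorded-neuron RF
#' direction, and intra-saccadic spike counting in the 0--20 ms window. The
#' result is the movement-level table that [fit_amplitude_model()],
#' [fit_interaction_model()] and [eccentricity_slope_profile()] consume.
#'
#' @param bundle a `session_bundle`.
#' @param cfg an [analysis_config()].
#' @param params a [detect_params()] list.
#' @param mode,window,first_only movement selection, see
#'   [select_movements()].
#' @param saccades optional pre-computed [detect_session()] result.
#' @return data.frame with one row per selected movement: `trial_id`,
#'   `neuron_id`, `ecc`, `onset_ms`, `onset_rel_stim_ms`, `amplitude`,
#'   `direction_deg`, `direction_class`, `count`.
#' @export
movement_records <- function(bundle, cfg = analysis_config(),
                             params = detect_params(),
                             mode = "post_stimulus", window = c(0, 200),
                             first_only = (mode == "post_stimulus"),
                             saccades = NULL) {
  if (is.null(saccades)) saccades <- detect_session(bundle, params)
  sel <- select_movements(saccades, bundle$trials, cfg, mode = mode,
                          window = window, first_only = first_only)
  if (!nrow(sel)) {
    return(data.frame(trial_id = integer(), neuron_id = character(),
                      ecc = numeric(), onset_ms = numeric(),
                      onset_rel_stim_ms = numeric(), amplitude = numeric(),
                      direction_deg = numeric(),
                      direction_class = character(), count = integer()))
  }
  ti <- match(sel$trial_id, bundle$trials$trial_id)
  nid <- bundle$trials$neuron_id[ti]
  ni <- match(nid, bundle$neurons$neuron_id)
  rf_dir <- bundle$neurons$rf_dir_deg[ni]
  cls <- vapply(seq_len(nrow(sel)), function(i) {
    classify_direction(sel$direction_deg[i], rf_dir[i],
                       cfg$toward_halfwidth)
  }, character(1))
  spk <- bundle$spikes
  key <- paste(spk$trial_id, spk$neuron_id)
  spl <- split(spk$time_ms, key)
  w <- cfg$intra_saccadic_window
  cnt <- vapply(seq_len(nrow(sel)), function(i) {
    st <- spl[[paste(sel$trial_id[i], nid[i])]]
    if (is.null(st)) return(0L)
    as.integer(sum(st >= sel$onset_ms[i] + w[1] &
                     st < sel$onset_ms[i] + w[2]))
  }, integer(1))
  data.frame(trial_id = sel$trial_id, neuron_id = nid,
             ecc = bundle$neurons$rf_ecc_deg[ni],
             onset_ms = sel$onset_ms,
             onset_rel_stim_ms = sel$onset_rel_stim_ms,
             amplitude = sel$amplitude_deg,
             direction_deg = sel$direction_deg,
             direction_class = cls, count = cnt)
}

#' Per-neuron stimulus-aligned rate curves and their population average
#'
#' Builds one trial-averaged firing-rate curve per neuron (aligned to
#' stimulus onset), normalizes each by its own peak, and averages across
#' neurons.
#'
#' @param bundle a `session_bundle`.
#' @param window ms relative to stimulus onset.
#' @param cfg an [analysis_config()].
#' @return list with `curves` (per neuron), `peaks` (per-neuron reference
#'   peaks) and `population` (see [population_average()]).
#' @export
population_rate_curves <- function(bundle, window = c(-100, 150),
                                   cfg = analysis_config()) {
  key <- paste(bundle$spikes$trial_id, bundle$spikes$neuron_id)
  spl <- split(bundle$spikes$time_ms, key)
  curves <- list()
  peaks <- numeric(0)
  for (nid in bundle$neurons$neuron_id) {
    tr <- bundle$trials[bundle$trials$neuron_id == nid, , drop = FALSE]
    if (!nrow(tr)) next
    trains <- lapply(seq_len(nrow(tr)), function(i) {
      st <- spl[[paste(tr$trial_id[i], nid)]]
      if (is.null(st)) numeric(0) else st
    })
    rc <- rate_curve(trains, tr$stimulus_onset_ms, window,
                     kernel_sd = cfg$rate_kernel_sd)
    pk <- max(rc$rate)
    if (!is.finite(pk) || pk <= 0) next
    curves[[nid]] <- rc
    peaks[nid] <- pk
  }
  if (!length(curves)) stop("no neuron produced a usable curve",
                            call. = FALSE)
  list(curves = curves, peaks = peaks,
       population = population_average(curves, peaks))
}

#' Spike trains of one neuron indexed by trial
#'
#' Convenience accessor returning a named list (trial id to spike-time
#' vector) for the trials recorded with `neuron_id`, as consumed by
#' [spike_timecourse_by_amplitude()] and [build_movement_rf()].
#'
#' @param bundle a `session_bundle`.
#' @param neuron_id neuron to extract; defaults to each trial's own recorded
#'   neuron (so the list covers every trial).
#' @return named list of numeric vectors.
#' @export
trial_trains <- function(bundle, neuron_id = NULL) {
  spk <- bundle$spikes
  if (!is.null(neuron_id)) {
    spk <- spk[spk$neuron_id == neuron_id, , drop = FALSE]
  } else {
    rec <- bundle$trials$neuron_id[match(spk$trial_id,
                                         bundle$trials$trial_id)]
    spk <- spk[spk$neuron_id == rec, , drop = FALSE]
  }
  spl <- split(spk$time_ms, spk$trial_id)
  out <- stats::setNames(vector("list", nrow(bundle$trials)),
                         as.character(bundle$trials$trial_id))
  for (k in names(spl)) out[[k]] <- spl[[k]]
  out
}
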