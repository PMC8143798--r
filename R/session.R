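#' Construct and validate a session bundle
#'
#' A session bundle holds everything recorded in one experimental session:
#' the trial table, the neuron metadata table, the long-format spike table and
#' one eye-position trace per trial. All time stamps are in ms relative to
#' trial start; positions are in degrees.
#'
#' @param session_id character scalar.
#' @param sampling_rate sampling rate of the eye traces in Hz (> 0).
#' @param trials data.frame with columns `trial_id`, `stimulus_onset_ms`,
#'   `condition`, `condition_value`, `neuron_id` (the neuron recorded on that
#'   trial).
#' @param neurons data.frame with columns `neuron_id`, `cls` (one of
#'   `"visual"`, `"visual_motor"`, `"rostral_motor"`), `site` (`"rostral"` or
#'   `"caudal"`), `rf_ecc_deg`, `rf_dir_deg`.
#' @param spikes data.frame with columns `trial_id`, `neuron_id`, `time_ms`.
#' @param eye named list (one entry per trial id) of matrices with columns
#'   `time_ms`, `x_deg`, `y_deg`.
#' @param ground_truth optional data.frame of generator ground truth; carried
#'   along but not serialized.
#' @return An object of class `session_bundle`.
#' @export
session_bundle <- function(session_id, sampling_rate, trials, neurons, spikes,
                           eye, ground_truth = NULL) {
  b <- structure(
    list(session_id = as.character(session_id),
         sampling_rate = as.numeric(sampling_rate),
         trials = as.data.frame(trials),
         neurons = as.data.frame(neurons),
         spikes = as.data.frame(spikes),
         eye = eye,
         ground_truth = ground_truth),
    class = "session_bundle")
  validate_session_bundle(b)
  b
}

validate_session_bundle <- function(b) {
  if (!is.finite(b$sampling_rate) || b$sampling_rate <= 0) {
    stop("sampling_rate must be positive", call. = FALSE)
  }
  need <- function(df, cols, nm) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      stop(sprintf("%s table is missing columns: %s", nm,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  need(b$trials, c("trial_id", "stimulus_onset_ms", "condition",
                   "condition_value", "neuron_id"), "trials")
  need(b$neurons, c("neuron_id", "cls", "site", "rf_ecc_deg", "rf_dir_deg"),
       "neurons")
  need(b$spikes, c("trial_id", "neuron_id", "time_ms"), "spikes")
  if (anyDuplicated(b$trials$trial_id)) {
    stop("trial ids must be unique", call. = FALSE)
  }
  bad <- setdiff(unique(b$trials$neuron_id), b$neurons$neuron_id)
  if (length(bad)) {
    stop("trials reference unknown neuron ids: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(b$spikes$neuron_id), b$neurons$neuron_id)
  if (length(bad)) {
    stop("spikes reference unknown neuron ids: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(b$spikes$trial_id), b$trials$trial_id)
  if (length(bad)) {
    stop("spikes reference unknown trial ids: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  caudal <- b$neurons$site == "caudal"
  if (any(caudal & (!is.finite(b$neurons$rf_ecc_deg) |
                    b$neurons$rf_ecc_deg <= 0))) {
    stop("caudal neurons need a finite positive rf_ecc_deg", call. = FALSE)
  }
  if (any(b$neurons$rf_dir_deg < 0 | b$neurons$rf_dir_deg >= 360)) {
    stop("rf_dir_deg must lie in [0, 360)", call. = FALSE)
  }
  if (!is.list(b$eye)) stop("eye must be a list of traces", call. = FALSE)
  miss <- setdiff(as.character(b$trials$trial_id), names(b$eye))
  if (length(miss)) {
    stop("missing eye traces for trials: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  invisible(b)
}

#' @export
print.session_bundle <- function(x, ...) {
  cat(sprintf("<session_bundle '%s'> %d trials, %d neurons, %d spikes, %g Hz\n",
              x$session_id, nrow(x$trials), nrow(x$neurons), nrow(x$spikes),
              x$sampling_rate))
  invisible(x)
}

#' Write a session bundle to a directory of delimited-text files
#'
#' Layout: `session.csv` (session_id, sampling_rate_hz), `trials.csv`,
#' `neurons.csv`, `spikes.csv`, and one `eye_<trial_id>.csv` per trial with
#' columns `time_ms, x_deg, y_deg`. Numbers are written at full precision so
#' that a write/read/write cycle is byte-identical.
#'
#' @param bundle a `session_bundle`.
#' @param path directory to create/fill.
#' @export
write_session <- function(bundle, path) {
  validate_session_bundle(bundle)
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", path, call. = FALSE)
  }
  fw <- function(df, file) {
    data.table::fwrite(df, file.path(path, file))
  }
  fw(data.frame(session_id = bundle$session_id,
                sampling_rate_hz = bundle$sampling_rate), "session.csv")
  fw(bundle$trials, "trials.csv")
  fw(bundle$neurons, "neurons.csv")
  fw(bundle$spikes, "spikes.csv")
  for (tid in as.character(bundle$trials$trial_id)) {
    tr <- bundle$eye[[tid]]
    fw(as.data.frame(tr), sprintf("eye_%s.csv", tid))
  }
  invisible(NULL)
}

#' Read a session bundle written by [write_session()]
#'
#' @param path directory containing the session files.
#' @return A validated `session_bundle`.
#' @export
read_session <- function(path) {
  fr <- function(file) {
    fp <- file.path(path, file)
    if (!file.exists(fp)) {
      stop("session load error: missing file '", file, "' in ", path,
           call. = FALSE)
    }
    as.data.frame(data.table::fread(fp))
  }
  meta <- fr("session.csv")
  trials <- fr("trials.csv")
  neurons <- fr("neurons.csv")
  spikes <- fr("spikes.csv")
  if (nrow(spikes) == 0L) {
    spikes <- data.frame(trial_id = integer(), neuron_id = character(),
                         time_ms = numeric())
  }
  eye <- list()
  for (tid in as.character(trials$trial_id)) {
    tr <- fr(sprintf("eye_%s.csv", tid))
    eye[[tid]] <- as.matrix(tr[, c("time_ms", "x_deg", "y_deg")])
  }
  session_bundle(meta$session_id[1], meta$sampling_rate_hz[1],
                 trials, neurons, spikes, eye)
}
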