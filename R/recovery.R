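#' Movement records from independently seeded fixture chunks
#'
#' Parameter-recovery runs need tens of thousands of trials; generating them
#' as a sequence of moderate, independently seeded sessions keeps memory flat
#' (each chunk's eye traces are discarded after detection) while leaving the
#' pooled movement table statistically identical to one long session.
#'
#' @param name fixture name (see [fixture_config()]).
#' @param seed master seed; chunk seeds are derived deterministically.
#' @param total_trials total trials across chunks.
#' @param chunk_trials trials per chunk.
#' @param mode,window movement selection, see [select_movements()].
#' @param cfg an [analysis_config()].
#' @param params a [detect_params()] list.
#' @param stream integer offset separating the random streams of different
#'   recovery experiments run from one master seed.
#' @return pooled [movement_records()] data.frame (trial ids are unique
#'   within, not across, chunks; a `chunk` column disambiguates).
#' @export
fixture_movement_records <- function(name, seed, total_trials,
                                     chunk_trials = 2000,
                                     mode = "post_stimulus",
                                     window = c(0, 200),
                                     cfg = analysis_config(),
                                     params = detect_params(),
                                     stream = 0L) {
  n_chunks <- ceiling(total_trials / chunk_trials)
  out <- vector("list", n_chunks)
  for (k in seq_len(n_chunks)) {
    b <- make_fixture(name, seed = chunk_seed(seed, k, stream),
                      n_trials = min(chunk_trials,
                                     total_trials - (k - 1) * chunk_trials))
    r <- movement_records(b, cfg, params, mode = mode, window = window)
    if (nrow(r)) r$chunk <- k
    out[[k]] <- r
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# deterministic chunk seeds below 2^31
chunk_seed <- function(seed, k, stream = 0L) {
  as.integer((abs(as.numeric(seed)) %% 50000) * 40000 + stream * 2000 + k)
}
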