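#' Write a session bundle to a plain-text directory
#'
#' Serializes the measured quantities of a `session_bundle` (units, spike
#' times, EMG envelope, trial table, duration) as CSV files plus a small
#' JSON-like metadata file. Ground-truth latent time courses are not
#' serialized (they are cheap to regenerate from the config seed); the
#' ground-truth delays, onsets and coupling table are.
#'
#' @param bundle a `session_bundle`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "session_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$units, file.path(dir, "units.csv"), row.names = FALSE)
  sp <- data.frame(
    unit_id = rep(bundle$units$unit_id, vapply(bundle$spikes, length, 1L)),
    time = unlist(bundle$spikes, use.names = FALSE))
  utils::write.csv(sp, file.path(dir, "spikes.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$emg), file.path(dir, "emg.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$trials, file.path(dir, "trials.csv"), row.names = FALSE)
  meta <- c(sprintf("duration,%0.6f", bundle$duration),
            sprintf("emg_rate,%d", bundle$emg_rate),
            sprintf("truth_delays,%s",
                    paste(bundle$truth$delays, collapse = ";")),
            sprintf("truth_onsets,%s",
                    paste(bundle$truth$onsets, collapse = ";")))
  writeLines(meta, file.path(dir, "meta.csv"))
  invisible(dir)
}

#' Read a session bundle written by [write_session_bundle()]
#'
#' @param dir directory path.
#' @return a `session_bundle` (without regenerated latent ground truth).
#' @export
read_session_bundle <- function(dir) {
  units <- utils::read.csv(file.path(dir, "units.csv"))
  sp <- utils::read.csv(file.path(dir, "spikes.csv"))
  spikes <- lapply(units$unit_id, function(u) sort(sp$time[sp$unit_id == u]))
  emg <- as.matrix(utils::read.csv(file.path(dir, "emg.csv")))
  trials <- utils::read.csv(file.path(dir, "trials.csv"))
  meta <- strsplit(readLines(file.path(dir, "meta.csv")), ",")
  mv <- setNames(vapply(meta, `[`, "", 2), vapply(meta, `[`, "", 1))
  num <- function(s) as.numeric(strsplit(s, ";")[[1]])
  bundle <- list(units = units, spikes = spikes, emg = emg,
                 emg_rate = as.integer(mv[["emg_rate"]]),
                 trials = trials,
                 duration = as.numeric(mv[["duration"]]),
                 truth = list(delays = num(mv[["truth_delays"]]),
                              onsets = num(mv[["truth_onsets"]])),
                 config = NULL)
  class(bundle) <- "session_bundle"
  bundle
}
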