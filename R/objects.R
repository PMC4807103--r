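#' Construct an epoch set
#'
#' Container for one subject/session's epoched voltages.
#'
#' @param data numeric array, channels x samples x trials, in microvolts.
#' @param sampling_rate sampling rate in Hz.
#' @param epoch_window numeric pair, epoch start/end in ms relative to cue
#'   onset (must span 0).
#' @param trial_flags character vector, one status per trial: `"accepted"`,
#'   `"amplitude_rejected"`, `"emg_excluded"` or `"error_trial"`.
#' @param montage_ref optional montage identifier (e.g. number of channels).
#' @return object of class `epoch_set`.
#' @export
epoch_set <- function(data, sampling_rate, epoch_window,
                      trial_flags = NULL, montage_ref = NULL) {
  stopifnot(length(dim(data)) == 3, length(epoch_window) == 2,
            epoch_window[1] < 0, epoch_window[2] > 0)
  n_samples <- dim(data)[2]
  expected <- round(diff(epoch_window) * sampling_rate / 1000) + 1
  if (abs(n_samples - expected) > 1)
    stop("sample count inconsistent with epoch window and sampling rate")
  flags <- trial_flags %||% rep("accepted", dim(data)[3])
  stopifnot(length(flags) == dim(data)[3])
  bad <- setdiff(unique(flags),
                 c("accepted", "amplitude_rejected", "emg_excluded",
                   "error_trial"))
  if (length(bad)) stop("unknown trial flag: ", paste(bad, collapse = ", "))
  structure(
    list(data = data, sampling_rate = sampling_rate,
         epoch_window = epoch_window,
         times = seq(epoch_window[1], by = 1000 / sampling_rate,
                     length.out = n_samples),
         trial_flags = flags, montage_ref = montage_ref),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> %d ch x %d samples x %d trials @ %g Hz, window %g..%g ms\n",
    d[1], d[2], d[3], x$sampling_rate, x$epoch_window[1], x$epoch_window[2]))
  print(table(x$trial_flags))
  invisible(x)
}

#' Construct an ERP (trial- or subject-averaged potentials)
#'
#' @param data channels x samples matrix of microvolt potentials.
#' @param sampling_rate Hz.
#' @param epoch_window ms pair.
#' @param n_trials number of trials (or subjects) averaged.
#' @param level `"subject"` or `"group"`.
#' @return object of class `erp`.
#' @export
erp <- function(data, sampling_rate, epoch_window, n_trials,
                level = c("subject", "group")) {
  level <- match.arg(level)
  structure(
    list(data = data, sampling_rate = sampling_rate,
         epoch_window = epoch_window,
         times = seq(epoch_window[1], by = 1000 / sampling_rate,
                     length.out = ncol(data)),
         n_trials = n_trials, level = level),
    class = "erp")
}

#' @export
print.erp <- function(x, ...) {
  cat(sprintf("<erp> %s-level, %d ch x %d samples @ %g Hz, n = %d\n",
              x$level, nrow(x$data), ncol(x$data), x$sampling_rate,
              x$n_trials))
  invisible(x)
}

# Run expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
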