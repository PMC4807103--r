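#' Write an epoch set as a delimited-text container
#'
#' Layout: `<dir>/meta.json` (sampling rate, epoch window, trial flags,
#' units microvolts, time axis ms) and `<dir>/data.tsv`, a channels x
#' (samples * trials) matrix with trials concatenated along columns,
#' trial-major (columns 1..S are trial 1, etc.).
#'
#' @param epochs an [epoch_set()].
#' @param dir output directory (created if needed).
#' @export
write_epochs <- function(epochs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(epochs$data)
  meta <- list(n_channels = d[1], n_samples = d[2], n_trials = d[3],
               sampling_rate = epochs$sampling_rate,
               epoch_window = epochs$epoch_window,
               trial_flags = epochs$trial_flags,
               units = "microvolt", time_axis = "ms",
               layout = "channels x (samples * trials), trial-major")
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  flat <- matrix(epochs$data, d[1], d[2] * d[3])
  utils::write.table(flat, file.path(dir, "data.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Read an epoch set written by [write_epochs()]
#'
#' @param dir container directory.
#' @return an [epoch_set()].
#' @export
read_epochs <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  flat <- as.matrix(utils::read.table(file.path(dir, "data.tsv"),
                                      sep = "\t", header = FALSE))
  dimnames(flat) <- NULL
  data <- array(flat, dim = c(meta$n_channels, meta$n_samples,
                              meta$n_trials))
  epoch_set(data, meta$sampling_rate, meta$epoch_window, meta$trial_flags)
}

#' Export an ERP as delimited text
#'
#' Rows are channels, columns are time points; the header row carries the
#' time axis in ms.
#'
#' @param x an [erp()].
#' @param path output path.
#' @param montage optional montage for channel labels.
#' @export
write_erp <- function(x, path, montage = NULL) {
  m <- x$data
  rownames(m) <- if (!is.null(montage)) montage$labels else
    sprintf("ch%03d", seq_len(nrow(m)))
  colnames(m) <- sprintf("%g", x$times)
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Read an ERP written by [write_erp()]
#'
#' @param path input path.
#' @param sampling_rate Hz (the file stores the ms axis; the rate is
#'   validated against it).
#' @param n_trials recorded trial count (metadata only).
#' @param level `"subject"` or `"group"`.
#' @return an [erp()].
#' @export
read_erp <- function(path, sampling_rate = NULL, n_trials = 1,
                     level = "subject") {
  m <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                         check.names = FALSE)
  times <- as.numeric(colnames(m))
  step <- stats::median(diff(times))
  rate <- 1000 / step
  if (!is.null(sampling_rate) && abs(rate - sampling_rate) > 1e-6)
    stop("time axis in file inconsistent with sampling_rate")
  erp(as.matrix(m), rate, c(times[1], times[length(times)]),
      n_trials = n_trials, level = level)
}
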