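#' Zero-phase band-pass filter
#'
#' Butterworth band-pass (default 1--30 Hz, 4th-order transfer function)
#' applied with zero phase: the filter's forward-backward (magnitude
#' squared) frequency response is applied in the frequency domain,
#' vectorized over channels, which is equivalent to running the IIR filter
#' forward and backward over each channel but free of its edge transients.
#' Edges are handled by odd-symmetric reflection padding of up to one
#' second.
#'
#' @param x numeric vector, channels x samples matrix, or `epoch_set`.
#' @param sampling_rate Hz (taken from the object when `x` is an
#'   `epoch_set`).
#' @param low_hz,high_hz band edges in Hz.
#' @param order filter order of the band-pass transfer function (even).
#' @return filtered object of the same shape.
#' @export
bandpass <- function(x, sampling_rate, low_hz = 1, high_hz = 30, order = 4) {
  UseMethod("bandpass")
}

#' @export
bandpass.numeric <- function(x, sampling_rate, low_hz = 1, high_hz = 30,
                             order = 4) {
  drop(bandpass(matrix(x, nrow = 1), sampling_rate, low_hz, high_hz, order))
}

#' @export
bandpass.matrix <- function(x, sampling_rate, low_hz = 1, high_hz = 30,
                            order = 4) {
  flt <- design_bandpass(sampling_rate, low_hz, high_hz, order)
  n <- ncol(x)
  np0 <- min(n - 1L, as.integer(sampling_rate))
  # round the padded length up to an FFT-friendly size
  tot <- stats::nextn(n + 2L * np0, c(2, 3, 5)) - n
  np <- min(n - 1L, tot %/% 2L)
  nq <- min(n - 1L, tot - np)
  xp <- if (np > 0) {
    cbind(2 * x[, 1] - x[, (np + 1):2, drop = FALSE],
          x,
          2 * x[, n] - x[, (n - 1):(n - nq), drop = FALSE])
  } else x
  nt <- ncol(xp)
  gain <- zero_phase_gain(flt, nt)
  # the gain is real, so two real channels ride one complex FFT
  # (one in the real part, one in the imaginary part)
  nr <- nrow(xp)
  if (nr == 1L) {
    f <- stats::fft(drop(xp)) * gain
    y <- matrix(Re(stats::fft(f, inverse = TRUE)) / nt, 1L)
    return(y[, (np + 1):(np + n), drop = FALSE])
  }
  half <- (nr + 1L) %/% 2L
  im_rows <- c(seq.int(half + 1L, nr), 1L)[seq_len(half)]
  z <- t(xp[seq_len(half), , drop = FALSE]) +
    1i * t(xp[im_rows, , drop = FALSE])
  z <- stats::mvfft(stats::mvfft(z) * gain, inverse = TRUE) / nt
  y <- matrix(0, nr, nt)
  y[seq_len(half), ] <- t(Re(z))
  y[seq.int(half + 1L, nr), ] <- t(Im(z))[seq_len(nr - half), , drop = FALSE]
  y[, (np + 1):(np + n), drop = FALSE]
}

#' @export
bandpass.epoch_set <- function(x, sampling_rate = x$sampling_rate,
                               low_hz = 1, high_hz = 30, order = 4) {
  d <- dim(x$data)
  # rows are independent for the filter: stack channels of all trials
  flat <- matrix(aperm(x$data, c(1, 3, 2)), d[1] * d[3], d[2])
  flat <- bandpass(flat, sampling_rate, low_hz, high_hz, order)
  x$data <- aperm(array(flat, c(d[1], d[3], d[2])), c(1, 3, 2))
  x
}

design_bandpass <- function(sampling_rate, low_hz, high_hz, order) {
  if (high_hz >= sampling_rate / 2)
    stop("high_hz must be below the Nyquist frequency")
  stopifnot(low_hz > 0, low_hz < high_hz, order %% 2 == 0)
  signal::butter(order / 2, c(low_hz, high_hz) / (sampling_rate / 2),
                 type = "pass")
}

# |H(w)|^2 of the discrete filter on the n-point DFT grid (forward-backward
# response: real, zero phase).
zero_phase_gain <- function(flt, n) {
  w <- 2 * pi * (seq_len(n) - 1) / n
  z <- exp(-1i * w)
  H <- outer(z, seq_along(flt$b) - 1, `^`) %*% flt$b /
    (outer(z, seq_along(flt$a) - 1, `^`) %*% flt$a)
  drop(abs(H)^2)
}

#' Re-reference to the average reference
#'
#' Subtracts, at every time sample, the mean over channels; channel
#' differences are unchanged and the per-sample channel mean becomes zero.
#' Idempotent.
#'
#' @param x numeric vector (one map), channels x samples matrix, `erp`, or
#'   `epoch_set`.
#' @return re-referenced object of the same shape.
#' @export
rereference_average <- function(x) UseMethod("rereference_average")

#' @export
rereference_average.numeric <- function(x) {
  if (length(x) < 2) stop("average reference needs at least 2 channels")
  x - mean(x)
}

#' @export
rereference_average.matrix <- function(x) {
  if (nrow(x) < 2) stop("average reference needs at least 2 channels")
  sweep(x, 2, colMeans(x))
}

#' @export
rereference_average.erp <- function(x) {
  x$data <- rereference_average(x$data)
  x
}

#' @export
rereference_average.epoch_set <- function(x) {
  d <- dim(x$data)
  mu <- colMeans(x$data)                      # samples x trials channel means
  x$data <- x$data - aperm(array(mu, c(d[2], d[3], d[1])), c(3, 1, 2))
  x
}

#' Automated amplitude-threshold artifact rejection
#'
#' Flags as `amplitude_rejected` every currently accepted trial in which any
#' channel at any sample exceeds `threshold_uv` in absolute value.
#' Previously excluded trials (EMG, error) keep their flags.
#'
#' @param epochs an `epoch_set`.
#' @param threshold_uv rejection criterion in microvolts (default 65).
#' @return the `epoch_set` with updated `trial_flags`.
#' @export
reject_amplitude <- function(epochs, threshold_uv = 65) {
  stopifnot(inherits(epochs, "epoch_set"), threshold_uv > 0)
  maxabs <- apply(abs(epochs$data), 3, max)
  reject <- epochs$trial_flags == "accepted" & maxabs > threshold_uv
  epochs$trial_flags[reject] <- "amplitude_rejected"
  epochs
}

#' Enforce the minimum accepted-trial count
#'
#' A subject/session dataset is usable only if it retains at least
#' `min_trials` accepted artifact-free trials (default floor 80).
#'
#' @param epochs an `epoch_set` (after rejection).
#' @param min_trials the floor.
#' @return list with `usable` (logical) and `n_accepted`.
#' @export
enforce_trial_floor <- function(epochs, min_trials = 80) {
  n_acc <- sum(epochs$trial_flags == "accepted")
  list(usable = n_acc >= min_trials, n_accepted = n_acc)
}

#' Average accepted trials into a subject ERP
#'
#' @param epochs an `epoch_set`; only trials flagged `accepted` enter the
#'   average.
#' @return a subject-level [erp()].
#' @export
average_trials <- function(epochs) {
  keep <- which(epochs$trial_flags == "accepted")
  if (length(keep) == 0) stop("no accepted trials to average")
  data <- rowMeans(epochs$data[, , keep, drop = FALSE], dims = 2)
  erp(data, epochs$sampling_rate, epochs$epoch_window,
      n_trials = length(keep), level = "subject")
}

#' Average subject ERPs into a group ERP
#'
#' Equal-weight arithmetic mean over subjects.
#'
#' @param erps non-empty list of subject-level [erp()] objects on identical
#'   channel/time axes.
#' @return a group-level [erp()].
#' @export
average_subjects <- function(erps) {
  if (length(erps) == 0) stop("no subject ERPs to average")
  dims <- vapply(erps, function(e) dim(e$data), numeric(2))
  if (any(dims != dims[, 1])) stop("subject ERPs have inconsistent axes")
  data <- Reduce(`+`, lapply(erps, `[[`, "data")) / length(erps)
  erp(data, erps[[1]]$sampling_rate, erps[[1]]$epoch_window,
      n_trials = length(erps), level = "group")
}

#' Preprocess one subject/session into an ERP
#'
#' Runs the fixed preprocessing chain in protocol order: band-pass filter →
#' average reference → amplitude rejection → trial floor →
#' spherical-spline interpolation of bad channels → trial averaging.  The
#' executed steps are recorded in the returned log.
#'
#' @param epochs raw `epoch_set`.
#' @param montage the recording [build_montage()].
#' @param bad_channels channels to interpolate (indices or labels).
#' @param low_hz,high_hz band-pass edges (default 1--30 Hz).
#' @param reject_uv amplitude criterion (default 65).
#' @param min_trials accepted-trial floor (default 80).
#' @param baseline_correct subtract the mean of the pre-stimulus segment
#'   (opt-in; default FALSE, the protocol applies none).
#' @return list with `erp` (NULL when unusable), `usable`, `n_accepted`,
#'   `epochs` (flagged), and `log` (character vector of executed steps).
#' @export
preprocess_subject <- function(epochs, montage, bad_channels = integer(0),
                               low_hz = 1, high_hz = 30, reject_uv = 65,
                               min_trials = 80, baseline_correct = FALSE) {
  log <- character(0)
  epochs <- bandpass(epochs, low_hz = low_hz, high_hz = high_hz)
  log <- c(log, sprintf("bandpass %g-%g Hz (zero-phase)", low_hz, high_hz))
  epochs <- rereference_average(epochs)
  log <- c(log, "average reference")
  epochs <- reject_amplitude(epochs, reject_uv)
  log <- c(log, sprintf("amplitude rejection at %g uV", reject_uv))
  floor <- enforce_trial_floor(epochs, min_trials)
  log <- c(log, sprintf("trial floor %d: %d accepted -> %s", min_trials,
                        floor$n_accepted,
                        if (floor$usable) "usable" else "unusable"))
  if (!floor$usable)
    return(list(erp = NULL, usable = FALSE, n_accepted = floor$n_accepted,
                epochs = epochs, log = log))
  if (length(bad_channels)) {
    epochs <- spherical_spline_interpolate(epochs, bad_channels, montage)
    epochs <- rereference_average(epochs)     # restore exact zero mean
    log <- c(log, sprintf("spherical-spline interpolation of %d channels",
                          length(resolve_channels(bad_channels, montage))))
  }
  out <- average_trials(epochs)
  log <- c(log, sprintf("averaged %d trials", out$n_trials))
  if (baseline_correct) {
    pre <- out$times < 0
    out$data <- out$data - rowMeans(out$data[, pre, drop = FALSE])
    log <- c(log, "baseline correction (pre-stimulus mean)")
  }
  list(erp = out, usable = TRUE, n_accepted = floor$n_accepted,
       epochs = epochs, log = log)
}
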