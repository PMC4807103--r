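#' Point-wise paired t-tests on ERP amplitudes
#'
#' Computes, at every channel and time sample, the paired t statistic on the
#' subject-wise difference of ERP amplitudes between two conditions, with
#' two-tailed p values from the t distribution with n−1 degrees of freedom.
#' Channel-samples with zero-variance differences have no defined t; their p
#' is set to 1 (and counted in the `n_zero_variance` attribute).
#'
#' @param erps_A,erps_B lists of subject-level [erp()] objects, same
#'   subjects in the same order, identical channel/time axes.
#' @return list with `t` and `p` (channels x samples matrices), `df`, and
#'   `n` (subjects).
#' @export
pointwise_paired_t <- function(erps_A, erps_B) {
  n <- length(erps_A)
  if (n != length(erps_B)) stop("condition A and B must pair the same subjects")
  if (n < 2) stop("paired t-test needs at least 2 subjects")
  d1 <- dim(erps_A[[1]]$data)
  D <- vapply(seq_len(n), function(s) {
    a <- erps_A[[s]]$data
    b <- erps_B[[s]]$data
    if (!identical(dim(a), d1) || !identical(dim(b), d1))
      stop("subject ERPs have inconsistent channel/time axes")
    a - b
  }, matrix(0, d1[1], d1[2]))
  mu <- rowMeans(D, dims = 2)
  resid <- D - as.vector(mu)            # recycles over the subject slab
  sdv <- sqrt(rowSums(resid^2, dims = 2) / (n - 1))
  tval <- mu / (sdv / sqrt(n))
  zero_var <- sdv == 0
  tval[zero_var] <- NA_real_
  p <- 2 * stats::pt(-abs(tval), df = n - 1)
  p[zero_var] <- 1
  structure(list(t = tval, p = p, df = n - 1, n = n),
            n_zero_variance = sum(zero_var))
}

#' Temporal-persistence criterion
#'
#' Per channel, clears significant runs shorter than `min_run_samples`
#' contiguous samples (e.g. 10 samples = 20 ms at 500 Hz); longer runs are
#' kept intact.
#'
#' @param significant logical channels x samples matrix (or logical vector).
#' @param min_run_samples minimum run length in samples.
#' @return filtered logical mask of the same shape.
#' @export
apply_temporal_criterion <- function(significant, min_run_samples = 10) {
  if (is.matrix(significant)) {
    t(apply(significant, 1, filter_runs, min_run = min_run_samples))
  } else {
    filter_runs(significant, min_run_samples)
  }
}

#' Spatial-cluster criterion
#'
#' At each time sample, groups the significant electrodes into
#' adjacency-connected components — evaluated within each of the nine named
#' scalp clusters by default — and clears components with fewer than
#' `min_electrodes` members.
#'
#' @param significant logical channels x samples matrix.
#' @param montage a [build_montage()] with adjacency and cluster partition.
#' @param min_electrodes minimum component size (default 5).
#' @param within_cluster restrict connectivity to electrodes of the same
#'   named cluster (default TRUE); FALSE uses the whole adjacency graph.
#' @return filtered logical mask.
#' @export
apply_spatial_criterion <- function(significant, montage, min_electrodes = 5,
                                    within_cluster = TRUE) {
  if (is.null(montage$clusters) && within_cluster)
    stop("montage lacks the nine-cluster partition")
  adjacency <- montage$adjacency
  if (within_cluster) {
    cl <- montage$clusters
    adjacency <- lapply(seq_along(adjacency), function(i)
      adjacency[[i]][cl[adjacency[[i]]] == cl[i]])
  }
  out <- significant
  for (s in seq_len(ncol(significant))) {
    members <- which(significant[, s])
    if (length(members) == 0) next
    keep <- logical(nrow(significant))
    for (comp in connected_components(adjacency, members))
      if (length(comp) >= min_electrodes) keep[comp] <- TRUE
    out[, s] <- keep
  }
  out
}

#' Mass-univariate waveform analysis between two conditions
#'
#' Point-wise paired t-tests followed by the temporal-persistence and
#' spatial-cluster criteria (temporal first, then spatial by default).
#'
#' @inheritParams pointwise_paired_t
#' @param montage recording [build_montage()].
#' @param alpha two-tailed significance level (default .05).
#' @param min_run_samples temporal criterion in samples (default 10, i.e.
#'   20 ms at 500 Hz).
#' @param min_electrodes spatial criterion (default 5 contiguous electrodes
#'   within one named cluster).
#' @param order `"temporal_first"` (default) or `"spatial_first"`.
#' @param within_cluster see [apply_spatial_criterion()].
#' @return object of class `significance_mask`: `t`, `p`, `significant`
#'   (filtered), `significant_raw` (pre-filter), parameters, and the
#'   filtering order used.
#' @export
waveform_analysis <- function(erps_A, erps_B, montage, alpha = 0.05,
                              min_run_samples = 10, min_electrodes = 5,
                              order = c("temporal_first", "spatial_first"),
                              within_cluster = TRUE) {
  order <- match.arg(order)
  tt <- pointwise_paired_t(erps_A, erps_B)
  raw <- tt$p < alpha
  mask <- raw
  if (order == "temporal_first") {
    mask <- apply_temporal_criterion(mask, min_run_samples)
    mask <- apply_spatial_criterion(mask, montage, min_electrodes,
                                    within_cluster)
  } else {
    mask <- apply_spatial_criterion(mask, montage, min_electrodes,
                                    within_cluster)
    mask <- apply_temporal_criterion(mask, min_run_samples)
  }
  structure(
    list(t_values = tt$t, p_values = tt$p, significant = mask,
         significant_raw = raw, alpha = alpha,
         min_run_samples = min_run_samples, min_electrodes = min_electrodes,
         order = order, clusters_used = levels(montage$clusters), df = tt$df),
    class = "significance_mask")
}

#' Export significant waveform intervals as delimited text
#'
#' One row per contiguous significant interval per electrode:
#' `electrode  start_ms  end_ms  peak_t` (tab-delimited, BED-like).
#'
#' @param mask a [waveform_analysis()] result.
#' @param times sample times in ms.
#' @param montage recording montage (for electrode labels).
#' @param path output path, or NULL to return the data frame only.
#' @return data frame of intervals, invisibly when written.
#' @export
export_significant_intervals <- function(mask, times, montage, path = NULL) {
  rows <- list()
  for (ch in seq_len(nrow(mask$significant))) {
    iv <- run_intervals(mask$significant[ch, ])
    if (nrow(iv) == 0) next
    for (r in seq_len(nrow(iv))) {
      seg <- iv[r, 1]:iv[r, 2]
      pk <- seg[which.max(abs(mask$t_values[ch, seg]))]
      rows[[length(rows) + 1L]] <- data.frame(
        electrode = montage$labels[ch], start_ms = times[iv[r, 1]],
        end_ms = times[iv[r, 2]], peak_t = mask$t_values[ch, pk])
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(electrode = character(0), start_ms = numeric(0),
               end_ms = numeric(0), peak_t = numeric(0))
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' @export
print.significance_mask <- function(x, ...) {
  cat(sprintf(
    "<significance_mask> %d ch x %d samples, alpha %g, run >= %d, >= %d electrodes (%s)\n",
    nrow(x$significant), ncol(x$significant), x$alpha, x$min_run_samples,
    x$min_electrodes, x$order))
  cat(sprintf("  significant channel-samples: %d (raw %d)\n",
              sum(x$significant), sum(x$significant_raw)))
  invisible(x)
}
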