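#' Global Field Power
#'
#' The spatial standard deviation of the scalp potential map at a time
#' point: the square root of the mean squared potential over electrodes,
#' measured against the average reference (the channel mean is subtracted
#' internally, making the index reference-free).
#'
#' @param x a map (numeric vector over channels), a channels x samples
#'   matrix, or an `erp`.
#' @return scalar for a single map, per-sample numeric vector otherwise.
#' @export
gfp <- function(x) UseMethod("gfp")

#' @export
gfp.numeric <- function(x) {
  if (length(x) < 2) stop("GFP needs at least 2 channels")
  x <- x - mean(x)
  sqrt(mean(x^2))
}

#' @export
gfp.matrix <- function(x) {
  if (nrow(x) < 2) stop("GFP needs at least 2 channels")
  x <- sweep(x, 2, colMeans(x))
  sqrt(colMeans(x^2))
}

#' @export
gfp.erp <- function(x) gfp(x$data)

#' Global map dissimilarity (DISS)
#'
#' Strength-independent index of topographic difference between two scalp
#' maps: each average-referenced map is scaled to unitary strength by its
#' instantaneous GFP, and DISS is the root mean squared difference of the
#' scaled maps.  Ranges from 0 (identical topographies) to 2 (inverted
#' topographies), with `DISS^2 = 2 (1 - r)` for spatial Pearson
#' correlation `r`.
#'
#' @param map_u,map_v numeric vectors over the same electrodes.
#' @return scalar in `[0, 2]`.
#' @export
diss <- function(map_u, map_v) {
  stopifnot(length(map_u) == length(map_v), length(map_u) >= 2)
  u <- map_u - mean(map_u)
  v <- map_v - mean(map_v)
  gu <- sqrt(mean(u^2))
  gv <- sqrt(mean(v^2))
  if (gu == 0 || gv == 0)
    stop("DISS undefined: a map has zero GFP (flat topography)")
  sqrt(mean((u / gu - v / gv)^2))
}

#' Point-wise paired randomization test on Global Field Power
#'
#' Tests, at every time sample, whether the electric field strength differs
#' between two paired conditions.  The observed statistic is the absolute
#' mean over subjects of the per-subject GFP difference; the null
#' distribution is built by independently exchanging each subject's
#' condition assignment (sign flip of the paired difference) in each of
#' `n_perm` permutations, with inclusive p counting
#' `p = (1 + #[perm >= obs]) / (n_perm + 1)`.  The temporal-persistence
#' criterion is applied to the `p < alpha` mask.
#'
#' @param erps_A,erps_B lists of subject-level [erp()] objects (paired, same
#'   order).
#' @param n_perm number of permutations per time point (default 1000).
#' @param alpha significance level (default .05).
#' @param min_run_samples persistence criterion in samples (default 10 =
#'   20 ms at 500 Hz).
#' @param seed integer seed for the permutation draws.
#' @return object of class `global_field_result` with per-sample `gfp_A`,
#'   `gfp_B` (group means of subject GFP), `statistic`, `p_values`,
#'   `significant` (after persistence filtering), `significant_windows`
#'   (ms intervals), and the test parameters.
#' @export
gfp_randomization_test <- function(erps_A, erps_B, n_perm = 1000,
                                   alpha = 0.05, min_run_samples = 10,
                                   seed = 1) {
  n <- check_paired(erps_A, erps_B, n_perm)
  GA <- t(vapply(erps_A, function(e) gfp(e$data), numeric(ncol(erps_A[[1]]$data))))
  GB <- t(vapply(erps_B, function(e) gfp(e$data), numeric(ncol(erps_B[[1]]$data))))
  D <- GA - GB                                  # n x samples
  obs <- abs(colMeans(D))
  E <- with_seed(substream_seed(seed, 271L),
                 matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                        n_perm, n))
  perm <- abs(E %*% D) / n                      # n_perm x samples
  b <- colSums(perm >= rep(obs, each = n_perm))
  p <- (b + 1) / (n_perm + 1)
  finish_gf_result(list(gfp_A = colMeans(GA), gfp_B = colMeans(GB),
                        statistic = obs, test = "gfp"),
                   p, erps_A[[1]], n_perm, alpha, min_run_samples, seed)
}

#' Topographic analysis of variance (TANOVA)
#'
#' Point-wise paired randomization test on global map dissimilarity: at each
#' time sample the observed statistic is the DISS between the two
#' condition-wise group-average maps (each scaled to unitary GFP), and the
#' null distribution is built by exchanging the condition labels within
#' subjects and recomputing the group averages for each of `n_perm`
#' permutations (inclusive p counting).  Samples at which a group-average
#' map has zero GFP get p = 1 and are counted in the result's
#' `n_zero_gfp`.  The 20 ms persistence criterion is applied as in the GFP
#' test.
#'
#' @inheritParams gfp_randomization_test
#' @param variant `"group"` (default): DISS between group-average maps,
#'   normalized at the group level; `"subject_normalized"`: single-subject
#'   maps are scaled to unitary GFP before group averaging.
#' @return a `global_field_result`; `diss` holds the per-sample observed
#'   statistic.
#' @export
tanova <- function(erps_A, erps_B, n_perm = 1000, alpha = 0.05,
                   min_run_samples = 10, seed = 1,
                   variant = c("group", "subject_normalized")) {
  variant <- match.arg(variant)
  n <- check_paired(erps_A, erps_B, n_perm)
  n_samp <- ncol(erps_A[[1]]$data)
  n_ch <- nrow(erps_A[[1]]$data)
  center <- function(m) sweep(m, 2, colMeans(m))
  norm_gfp <- function(m) {
    g <- sqrt(colMeans(m^2))
    sweep(m, 2, pmax(g, .Machine$double.xmin), "/")
  }
  prep <- function(e) {
    m <- center(e$data)
    if (variant == "subject_normalized") norm_gfp(m) else m
  }
  A <- lapply(erps_A, prep)
  B <- lapply(erps_B, prep)
  # per-subject sum and difference: group mean under a sign assignment
  # eps is  ( mean(M) + mean(eps * D) ) / 2  for condition A
  Darr <- array(0, dim = c(n_ch, n_samp, n))
  Msum <- matrix(0, n_ch, n_samp)
  for (s in seq_len(n)) {
    Darr[, , s] <- A[[s]] - B[[s]]
    Msum <- Msum + A[[s]] + B[[s]]
  }
  Mbar <- Msum / n
  E <- with_seed(substream_seed(seed, 547L),
                 matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                        n_perm, n))
  p <- numeric(n_samp)
  obs <- numeric(n_samp)
  zero_gfp <- logical(n_samp)
  for (t in seq_len(n_samp)) {
    Dt <- matrix(Darr[, t, ], n_ch, n)            # ch x subjects
    mA_obs <- (Mbar[, t] + rowMeans(Dt)) / 2
    mB_obs <- (Mbar[, t] - rowMeans(Dt)) / 2
    gA <- sqrt(mean((mA_obs)^2))
    gB <- sqrt(mean((mB_obs)^2))
    if (gA == 0 || gB == 0) {
      p[t] <- 1
      obs[t] <- NA_real_
      zero_gfp[t] <- TRUE
      next
    }
    obs[t] <- sqrt(mean((mA_obs / gA - mB_obs / gB)^2))
    Tt <- (E %*% t(Dt)) / n                       # n_perm x ch
    mA <- sweep(Tt, 2, Mbar[, t], "+") / 2
    mB <- sweep(-Tt, 2, Mbar[, t], "+") / 2
    gpA <- pmax(sqrt(rowMeans(mA^2)), .Machine$double.xmin)
    gpB <- pmax(sqrt(rowMeans(mB^2)), .Machine$double.xmin)
    dd <- sqrt(rowMeans((mA / gpA - mB / gpB)^2))
    p[t] <- (1 + sum(dd >= obs[t])) / (n_perm + 1)
  }
  res <- finish_gf_result(list(gfp_A = NULL, gfp_B = NULL, statistic = obs,
                               diss = obs, test = "tanova",
                               variant = variant),
                          p, erps_A[[1]], n_perm, alpha, min_run_samples,
                          seed)
  res$n_zero_gfp <- sum(zero_gfp)
  res
}

check_paired <- function(erps_A, erps_B, n_perm) {
  n <- length(erps_A)
  if (n != length(erps_B)) stop("conditions must pair the same subjects")
  if (n < 2) stop("need at least 2 paired subjects")
  if (n_perm < 100) stop("n_perm must be at least 100")
  d1 <- dim(erps_A[[1]]$data)
  ok <- vapply(c(erps_A, erps_B),
               function(e) identical(dim(e$data), d1), logical(1))
  if (!all(ok)) stop("subject ERPs have inconsistent channel/time axes")
  n
}

finish_gf_result <- function(base, p, ref_erp, n_perm, alpha,
                             min_run_samples, seed) {
  sig <- filter_runs(p < alpha, min_run_samples)
  iv <- run_intervals(sig)
  windows <- if (nrow(iv)) cbind(start_ms = ref_erp$times[iv[, 1]],
                                 end_ms = ref_erp$times[iv[, 2]])
             else cbind(start_ms = numeric(0), end_ms = numeric(0))
  structure(
    c(base,
      list(p_values = p, significant = sig, significant_windows = windows,
           times = ref_erp$times, n_permutations = n_perm, alpha = alpha,
           min_run_samples = min_run_samples, seed = seed)),
    class = "global_field_result")
}

#' @export
print.global_field_result <- function(x, ...) {
  cat(sprintf("<global_field_result> %s test, %d permutations, alpha %g\n",
              x$test, x$n_permutations, x$alpha))
  w <- x$significant_windows
  if (nrow(w) == 0) {
    cat("  no significant windows\n")
  } else {
    for (r in seq_len(nrow(w)))
      cat(sprintf("  significant window: %g..%g ms\n", w[r, 1], w[r, 2]))
  }
  invisible(x)
}

#' Plot GFP or DISS series with significant windows shaded
#'
#' Base-graphics summary of a [gfp_randomization_test()] or [tanova()]
#' result: the statistic series over time with the significant windows
#' shaded.
#'
#' @param x a `global_field_result`.
#' @param ... passed to [plot()].
#' @export
plot.global_field_result <- function(x, ...) {
  y <- if (x$test == "gfp") x$gfp_A else x$statistic
  ylab <- if (x$test == "gfp") "GFP (uV)" else "DISS"
  graphics::plot(x$times, y, type = "n", xlab = "time (ms)", ylab = ylab,
                 ...)
  w <- x$significant_windows
  for (r in seq_len(nrow(w)))
    graphics::rect(w[r, 1], graphics::par("usr")[3], w[r, 2],
                   graphics::par("usr")[4], col = "grey85", border = NA)
  graphics::lines(x$times, y)
  if (x$test == "gfp") graphics::lines(x$times, x$gfp_B, lty = 2)
  invisible(x)
}
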