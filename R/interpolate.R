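#' Spherical-spline interpolation of bad channels
#'
#' Replaces the values of bad channels by spherical-spline estimates computed
#' from the good channels (Perrin-style thin-plate spline on the sphere).
#' The spline kernel is the Legendre series
#' \eqn{g(x) = \frac{1}{4\pi}\sum_{n\ge 1} \frac{2n+1}{(n(n+1))^m} P_n(x)},
#' truncated at `n_terms`; the spline coefficients solve the regularized
#' interpolation system on the good channels with a zero-sum constraint, and
#' the bad channels are evaluated from the fitted spline.  Good channels are
#' returned unchanged.
#'
#' @param x an `erp`, an `epoch_set`, or a channels x samples matrix.
#' @param bad_channels integer indices or channel labels of channels to
#'   replace (strict subset of the montage).
#' @param montage the [build_montage()] the data were recorded with.
#' @param m spline stiffness order (default 4).
#' @param lambda smoothing (ridge) parameter added to the kernel diagonal
#'   (default 1e-5).
#' @param n_terms number of Legendre terms in the kernel series (default 50).
#' @return object of the same shape as `x` with bad channels replaced.
#' @export
spherical_spline_interpolate <- function(x, bad_channels, montage,
                                         m = 4, lambda = 1e-5, n_terms = 50) {
  UseMethod("spherical_spline_interpolate")
}

#' @export
spherical_spline_interpolate.matrix <- function(x, bad_channels, montage,
                                                m = 4, lambda = 1e-5,
                                                n_terms = 50) {
  bad <- resolve_channels(bad_channels, montage)
  if (length(bad) == 0L) return(x)
  n_ch <- nrow(x)
  stopifnot(n_ch == length(montage$labels))
  good <- setdiff(seq_len(n_ch), bad)
  if (length(good) < 8)
    stop("spherical-spline interpolation needs at least 8 good channels")
  op <- spline_operator(montage, good, bad, m, lambda, n_terms)
  x[bad, ] <- op %*% x[good, , drop = FALSE]
  x
}

#' @export
spherical_spline_interpolate.erp <- function(x, bad_channels, montage,
                                             m = 4, lambda = 1e-5,
                                             n_terms = 50) {
  x$data <- spherical_spline_interpolate(x$data, bad_channels, montage,
                                         m, lambda, n_terms)
  x
}

#' @export
spherical_spline_interpolate.epoch_set <- function(x, bad_channels, montage,
                                                   m = 4, lambda = 1e-5,
                                                   n_terms = 50) {
  bad <- resolve_channels(bad_channels, montage)
  if (length(bad) == 0L) return(x)
  good <- setdiff(seq_len(dim(x$data)[1]), bad)
  if (length(good) < 8)
    stop("spherical-spline interpolation needs at least 8 good channels")
  op <- spline_operator(montage, good, bad, m, lambda, n_terms)
  for (tr in seq_len(dim(x$data)[3]))
    x$data[bad, , tr] <- op %*% x$data[good, , tr]
  x
}

resolve_channels <- function(ch, montage) {
  if (is.character(ch)) ch <- match(ch, montage$labels)
  ch <- as.integer(ch)
  if (anyNA(ch) || any(ch < 1) || any(ch > length(montage$labels)))
    stop("unknown channel in bad_channels")
  if (length(ch) >= length(montage$labels))
    stop("bad_channels must be a strict subset of the montage")
  sort(unique(ch))
}

# Linear operator mapping good-channel values to bad-channel estimates.
# Solves [G + lambda I, 1; 1', 0] [c; c0] = [v; 0] on the good channels and
# evaluates c0 + G_bg c at the bad ones; both steps collapse into one matrix.
spline_operator <- function(montage, good, bad, m, lambda, n_terms) {
  P <- montage$positions / montage$head_radius
  gfun <- function(cosang) spline_g(cosang, m, n_terms)
  Cgg <- tcrossprod(P[good, , drop = FALSE])
  Cbg <- P[bad, , drop = FALSE] %*% t(P[good, , drop = FALSE])
  ng <- length(good)
  G <- gfun(pmin(pmax(Cgg, -1), 1)) + diag(lambda, ng)
  A <- rbind(cbind(G, 1), c(rep(1, ng), 0))
  Gi <- solve(A)
  Gb <- cbind(gfun(pmin(pmax(Cbg, -1), 1)), 1)   # [g(bad,good), 1]
  (Gb %*% Gi)[, seq_len(ng), drop = FALSE]
}

# Perrin g-function: (1/4pi) sum (2n+1)/(n(n+1))^m P_n(x), vectorized over x.
spline_g <- function(x, m, n_terms) {
  out <- array(0, dim = dim(x) %||% length(x))
  Pm1 <- array(1, dim = dim(out))
  P <- x
  for (n in seq_len(n_terms)) {
    out <- out + (2 * n + 1) / (n * (n + 1))^m * P
    if (n < n_terms) {
      Pn <- ((2 * n + 1) * x * P - n * Pm1) / (n + 1)
      Pm1 <- P
      P <- Pn
    }
  }
  out / (4 * pi)
}
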