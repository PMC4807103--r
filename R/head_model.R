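#' Three-shell spherical volume-conductor model
#'
#' An analytic concentric-spheres head model (brain, skull, scalp) for the
#' EEG forward problem.  Potentials are obtained from the Legendre-series
#' solution of the quasi-static Poisson equation: for each spherical-harmonic
#' order the radial continuity conditions (potential and normal current at
#' each shell boundary, zero normal current at the scalp surface) form a
#' small linear system whose solution yields a per-order transfer factor;
#' the dipole source term is the standard multipole expansion of the
#' free-medium dipole potential.
#'
#' @param radii increasing shell radii, innermost (brain) first, in
#'   normalized head units; default `c(0.87, 0.92, 1.0)`.
#' @param conductivities shell conductivities in the same order; default
#'   `c(1, 1/80, 1)` (brain : skull : scalp).
#' @param n_terms number of Legendre terms retained in the series.
#' @return object of class `head_model` with the transfer factors cached.
#' @export
head_model <- function(radii = c(0.87, 0.92, 1.0),
                       conductivities = c(1, 1 / 80, 1),
                       n_terms = 80) {
  stopifnot(length(radii) == length(conductivities), length(radii) >= 1,
            all(diff(radii) > 0), all(conductivities > 0), n_terms >= 10)
  hm <- structure(
    list(radii = radii, conductivities = conductivities, n_terms = n_terms,
         brain_radius = radii[1], scalp_radius = radii[length(radii)]),
    class = "head_model")
  hm$g <- vapply(seq_len(n_terms), function(n) shell_transfer(hm, n),
                 numeric(1))
  hm
}

# Surface response to a unit r^-(n+1) source harmonic inside the innermost
# shell: solves the boundary-condition system for Legendre order n and
# returns the potential coefficient at the scalp surface.
# Unknowns per shell k: alpha_k (r^n term) and, for k > 1, beta_k
# (r^-(n+1) term); shell 1 carries the known unit source coefficient.
shell_transfer <- function(hm, n) {
  a <- hm$radii
  s <- hm$conductivities
  L <- length(a)
  R <- a[L]
  if (L == 1) return((2 * n + 1) / n * R^(-(n + 1)))
  nu <- 2 * L - 1              # alpha_1..alpha_L, beta_2..beta_L
  A <- matrix(0, nu, nu)
  b <- numeric(nu)
  ai <- function(k) k                  # alpha_k index
  bi <- function(k) L + k - 1          # beta_k index (k >= 2)
  row <- 0
  for (k in seq_len(L - 1)) {          # boundary between shell k and k+1
    r <- a[k]
    # potential continuity
    row <- row + 1
    A[row, ai(k)] <- r^n
    if (k > 1) A[row, bi(k)] <- r^(-(n + 1))
    A[row, ai(k + 1)] <- -r^n
    A[row, bi(k + 1)] <- -r^(-(n + 1))
    if (k == 1) b[row] <- -r^(-(n + 1))      # source term lives in shell 1
    # normal-current continuity
    row <- row + 1
    A[row, ai(k)] <- s[k] * n * r^(n - 1)
    if (k > 1) A[row, bi(k)] <- -s[k] * (n + 1) * r^(-(n + 2))
    A[row, ai(k + 1)] <- -s[k + 1] * n * r^(n - 1)
    A[row, bi(k + 1)] <- s[k + 1] * (n + 1) * r^(-(n + 2))
    if (k == 1) b[row] <- s[1] * (n + 1) * r^(-(n + 2))
  }
  # insulating boundary at the scalp surface
  row <- row + 1
  A[row, ai(L)] <- n * R^(n - 1)
  A[row, bi(L)] <- -(n + 1) * R^(-(n + 2))
  # column equilibration: the mixed r^n / r^-(n+1) powers make the raw
  # system ill-conditioned at high orders
  cs <- apply(abs(A), 2, max)
  x <- solve(sweep(A, 2, cs, "/"), b) / cs
  x[ai(L)] * R^n + x[bi(L)] * R^(-(n + 1))
}

#' Scalp potentials of current dipoles in the spherical head model
#'
#' Computes the potential at scalp electrodes generated by one or more
#' current dipoles inside the brain sphere, via the Legendre-series solution.
#'
#' @param head a [head_model()].
#' @param positions dipole positions, n x 3 matrix (normalized head units,
#'   strictly inside the brain sphere).
#' @param moments dipole moments, n x 3 matrix (nA·m, arbitrary consistent
#'   scale).
#' @param electrodes electrode positions, m x 3 matrix on the scalp sphere
#'   (only their directions are used).
#' @param average_reference subtract the mean over electrodes from each
#'   dipole's potential vector (default TRUE).
#' @return m x n matrix of potentials, one column per dipole.
#' @export
dipole_potentials <- function(head, positions, moments, electrodes,
                              average_reference = TRUE) {
  positions <- rbind(positions)
  moments <- rbind(moments)
  stopifnot(ncol(positions) == 3, ncol(moments) == 3,
            nrow(positions) == nrow(moments))
  b <- sqrt(rowSums(positions^2))
  if (any(b >= head$brain_radius))
    stop("dipole position outside the brain sphere")
  E <- electrodes / sqrt(rowSums(electrodes^2))   # unit directions
  m <- nrow(E)
  np <- nrow(positions)
  U <- positions / ifelse(b > 1e-12, b, 1)
  U[b <= 1e-12, ] <- rep(c(0, 0, 1), each = sum(b <= 1e-12))
  cosg <- E %*% t(U)                              # m x np
  # accumulate A = sum_n g_n b^(n-1) n P_n(cosg),  B = sum_n g_n b^(n-1) P'_n
  Pm1 <- matrix(1, m, np)       # P_0
  P <- cosg                     # P_1
  dPm1 <- matrix(0, m, np)      # P'_0
  dP <- matrix(1, m, np)        # P'_1
  bw <- rep(1, np)              # b^(n-1), with 0^0 := 1
  Acc <- head$g[1] * sweep(P, 2, bw, "*")         # n = 1 term: n * P_1
  Bcc <- head$g[1] * sweep(dP, 2, bw, "*")
  for (n in 2:head$n_terms) {
    bw <- bw * b
    Pn <- ((2 * n - 1) * cosg * P - (n - 1) * Pm1) / n
    dPn <- dPm1 + (2 * n - 1) * P
    Pm1 <- P; P <- Pn
    dPm1 <- dP; dP <- dPn
    w <- head$g[n] * bw
    Acc <- Acc + n * sweep(P, 2, w, "*")
    Bcc <- Bcc + sweep(dP, 2, w, "*")
  }
  qr_ <- rowSums(moments * U)                     # radial moment (q . u)
  qe <- E %*% t(moments)                          # (q . e_hat), m x np
  V <- sweep(Acc, 2, qr_, "*") + Bcc * (qe - sweep(cosg, 2, qr_, "*"))
  V <- V / (4 * pi * head$conductivities[1])
  if (average_reference) V <- sweep(V, 2, colMeans(V), "-")
  V
}

#' @export
print.head_model <- function(x, ...) {
  cat(sprintf("<head_model> %d shells, radii %s, conductivities %s\n",
              length(x$radii), paste(signif(x$radii, 3), collapse = "/"),
              paste(signif(x$conductivities, 3), collapse = ":")))
  invisible(x)
}
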