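test_that("the source grid stays inside the brain with symmetric adjacency", {
  grid <- fx_grid_small()
  expect_true(all(sqrt(rowSums(grid$points^2)) < fx_head()$brain_radius))
  expect_gt(grid$n_points, 100)
  for (i in seq_len(grid$n_points))
    for (j in grid$neighbors[[i]])
      expect_true(i %in% grid$neighbors[[j]])
})

test_that("lead-field columns are average-referenced and linear", {
  lf <- fx_lf_small()
  expect_lt(max(abs(colMeans(lf$matrix))), 1e-12)
  grid <- fx_grid_small()
  p <- 10
  q <- c(0.5, -1, 2)
  v <- lf$matrix[, (p - 1) * 3 + 1:3] %*% q
  vref <- dipole_potentials(fx_head(), grid$points[p, ], q,
                            fx_mon32()$positions)
  expect_equal(drop(v), drop(vref), tolerance = 1e-10)
})

test_that("the LAURA inverse is linear, shrinks with lambda, and scales", {
  grid <- fx_grid_small()
  inv <- build_laura_inverse(fx_lf_small(), grid)
  zero <- apply_inverse(inv, rep(0, 32), lambda = 1)
  expect_equal(max(abs(zero$magnitude)), 0)
  set.seed(53)
  v <- rnorm(32); v <- v - mean(v)
  lams <- max(inv$eigenvalues) * 10^seq(-6, 2, by = 2)
  energy <- vapply(lams, function(l)
    sum(apply_inverse(inv, v, lambda = l)$magnitude^2), numeric(1))
  expect_true(all(diff(energy) < 0))              # monotone shrinkage
  a <- apply_inverse(inv, v, lambda = lams[2])
  b <- apply_inverse(inv, 2.5 * v, lambda = lams[2])
  expect_equal(b$magnitude, 2.5 * a$magnitude, tolerance = 1e-10)
})

test_that("a grid point without neighbours is a configuration error", {
  lone <- structure(
    list(points = rbind(c(0, 0, 0.2), c(0, 0, -0.2)), spacing = 0.05,
         neighbors = list(integer(0), integer(0)), n_points = 2),
    class = "source_grid")
  lf <- compute_lead_field(lone, fx_mon32(), fx_head())
  expect_error(build_laura_inverse(lf, lone), "no neighbours")
})

test_that("standardized mapping localizes noiseless point sources exactly", {
  grid <- fx_grid_small()
  lf <- fx_lf_small()
  inv <- build_sloreta_inverse(lf, grid)
  pts <- grid$points
  r <- sqrt(rowSums(pts^2))
  sup <- which(r > 0.5 & pts[, 3] > -0.1)
  set.seed(59)
  hits <- 0
  n_src <- 20
  for (i in seq_len(n_src)) {
    p <- sample(sup, 1)
    q <- rnorm(3); q <- q / sqrt(sum(q^2))
    v <- lf$matrix[, (p - 1) * 3 + 1:3] %*% q
    mag <- apply_inverse(inv, v,
                         lambda = max(inv$eigenvalues) * 1e-8)$magnitude
    d <- sqrt(sum((pts[which.max(mag), ] - pts[p, ])^2))
    if (d <= grid$spacing * 1.001) hits <- hits + 1
  }
  expect_gte(hits, ceiling(0.9 * n_src))
})

test_that("window averaging commutes with the linear inverse", {
  grid <- fx_grid_small()
  inv <- build_laura_inverse(fx_lf_small(), grid)
  set.seed(61)
  e <- erp(rereference_average(matrix(rnorm(32 * 40), 32)), 500,
           c(-20, 58), n_trials = 1)
  lam <- max(inv$eigenvalues) * 1e-4
  # single-sample window equals inverting that sample's map
  one <- estimate_window_activity(inv, e, c(10, 10), lambda = lam)
  expect_equal(one, drop(apply_inverse(inv, e$data[, e$times == 10],
                                       lambda = lam)$magnitude))
  # time-constant ERP: any window gives the same result
  ec <- erp(matrix(rep(e$data[, 1], 40), 32), 500, c(-20, 58), 1)
  expect_equal(estimate_window_activity(inv, ec, c(-20, 58), lambda = lam),
               estimate_window_activity(inv, ec, c(0, 10), lambda = lam),
               tolerance = 1e-10)
  # average-then-invert equals invert-then-average (moments are linear)
  sel <- e$times >= 0 & e$times <= 40
  m1 <- apply_inverse(inv, rowMeans(e$data[, sel]), lambda = lam)$moments
  m2 <- rowMeans(apply_inverse(inv, e$data[, sel], lambda = lam)$moments)
  expect_equal(drop(m1), m2, tolerance = 1e-10)
  expect_error(estimate_window_activity(inv, e, c(500, 600)), "no samples")
})

test_that("voxel-wise contrast applies t threshold and 10-point cluster rule", {
  grid <- fx_grid_small()
  n_sub <- 12
  base <- matrix(1, n_sub, grid$n_points)
  expect_equal(nrow(voxelwise_contrast(base, base, grid)$clusters), 0)
  set.seed(67)
  mk_act <- function(members) {
    A <- base
    # strong consistent effect at the member points only; elsewhere the
    # paired difference has exactly zero variance (p = 1 by convention)
    A[, members] <- A[, members] + 5 + matrix(rnorm(n_sub * length(members),
                                                    sd = 0.1),
                                              n_sub)
    A
  }
  grow <- function(size) {     # connected set via BFS from a central point
    start <- which.min(rowSums(grid$points^2))
    out <- integer(0); queue <- start
    seen <- logical(grid$n_points); seen[start] <- TRUE
    while (length(queue) && length(out) < size) {
      v <- queue[[1]]; queue <- queue[-1]; out <- c(out, v)
      nb <- grid$neighbors[[v]][!seen[grid$neighbors[[v]]]]
      seen[nb] <- TRUE; queue <- c(queue, nb)
    }
    out
  }
  nine <- grow(9); ten <- grow(10)
  expect_equal(nrow(voxelwise_contrast(mk_act(nine), base, grid)$clusters), 0)
  ct <- voxelwise_contrast(mk_act(ten), base, grid)
  expect_equal(nrow(ct$clusters), 1)
  expect_equal(sort(which(ct$significant)), sort(ten))
  expect_equal(ct$clusters$sign, 1)
  # opposite contrast produces the negative cluster; signs stay disjoint
  ct2 <- voxelwise_contrast(base, mk_act(ten), grid)
  expect_equal(ct2$clusters$sign, -1)
  expect_true(all(ct$t[ct$significant] > ct$t_critical))
  expect_equal(ct$t_critical, stats::qt(0.975, n_sub - 1))
})
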