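test_that("GFP is the reference-free spatial standard deviation", {
  expect_equal(gfp(c(1, -1)), 1)
  expect_equal(gfp(c(2, -2, 0, 0)), sqrt(2))
  set.seed(31)
  u <- rnorm(20)
  expect_equal(gfp(-3.2 * u), 3.2 * gfp(u))        # homogeneity
  expect_equal(gfp(u + 42), gfp(u))                # reference shift
  m <- matrix(rnorm(60), 10)
  expect_equal(gfp(m), apply(m, 2, gfp))
  expect_error(gfp(5), "2 channels")
})

test_that("DISS has the documented geometry", {
  set.seed(37)
  u <- rnorm(24); v <- rnorm(24)
  expect_equal(diss(u, u), 0)
  expect_equal(diss(u, -u), 2)
  expect_equal(diss(u, 3 * u), 0)                  # strength-independent
  expect_equal(diss(u, v), diss(v, u))             # symmetric
  expect_equal(diss(u, v), diss(2 * u + 5, v - 3), tolerance = 1e-12)
  expect_error(diss(u, rep(0, 24)), "zero GFP")
  # orthogonal (zero spatial correlation) maps sit at sqrt(2)
  uc <- u - mean(u)
  w <- rnorm(24); w <- w - mean(w)
  w <- w - sum(w * uc) / sum(uc^2) * uc            # project out u
  expect_equal(diss(u, w), sqrt(2), tolerance = 1e-12)
})

test_that("identical conditions produce no significant samples", {
  set.seed(41)
  A <- erps_from_array(array(rnorm(8 * 16 * 50), c(8, 16, 50)),
                       window = c(-20, 78))
  g <- gfp_randomization_test(A, A, n_perm = 200, seed = 1)
  expect_true(all(g$p_values == 1))
  expect_equal(nrow(g$significant_windows), 0)
  tn <- tanova(A, A, n_perm = 200, seed = 1)
  expect_true(all(tn$p_values == 1))
})

test_that("randomization tests are deterministic given the seed", {
  set.seed(43)
  A <- erps_from_array(array(rnorm(6 * 16 * 30), c(6, 16, 30)),
                       window = c(-10, 48))
  B <- erps_from_array(array(rnorm(6 * 16 * 30), c(6, 16, 30)),
                       window = c(-10, 48))
  t1 <- tanova(A, B, n_perm = 200, seed = 7)
  t2 <- tanova(A, B, n_perm = 200, seed = 7)
  expect_identical(t1$p_values, t2$p_values)
  t3 <- tanova(A, B, n_perm = 200, seed = 8)
  expect_false(identical(t1$p_values, t3$p_values))
})

test_that("a pure strength effect is invisible to TANOVA (noise-free)", {
  d <- suppressWarnings(sim_design(
    n_subjects = 6, n_trials_per_condition = 2, n_channels = 24,
    epoch_window = c(-100, 300), noise_sd = 0, artifact_rate = 0,
    emg_exclusion_rate = 0, error_trial_rate = 0, subject_gain_sd = 0.3,
    components = list(source_component(
      location = c(0.1290, 0, 0.6451), orientation = c(0, 0, 1),
      peak_ms = 150, fwhm_ms = 120, amplitude = 10,
      condition_gains = c(1.6, 1)))))
  ex <- simulate_experiment(d, head = fx_head())
  eA <- lapply(ex$subjects, function(su) average_trials(su$A))
  eB <- lapply(ex$subjects, function(su) average_trials(su$B))
  tn <- tanova(eA, eB, n_perm = 200, seed = 2)
  expect_true(all(is.na(tn$diss) | tn$diss < 1e-6))
  expect_equal(nrow(tn$significant_windows), 0)
  # while the GFP test detects the strength difference in the active window
  g <- gfp_randomization_test(eA, eB, n_perm = 200, seed = 2)
  pk <- which.min(abs(eA[[1]]$times - 150))
  expect_lt(g$p_values[pk], 0.05)
})

test_that("significant windows respect the persistence criterion", {
  set.seed(47)
  n <- 10; ch <- 16; s <- 60
  A <- array(rnorm(n * ch * s), c(n, ch, s))
  B <- array(rnorm(n * ch * s), c(n, ch, s))
  B[, 1:8, 20:40] <- B[, 1:8, 20:40] + 3          # sustained field change
  eA <- erps_from_array(A, window = c(-20, 98))
  eB <- erps_from_array(B, window = c(-20, 98))
  for (res in list(gfp_randomization_test(eA, eB, 300, seed = 3),
                   tanova(eA, eB, 300, seed = 3))) {
    w <- res$significant_windows
    expect_gt(nrow(w), 0)                         # sustained effect found
    len <- (w[, 2] - w[, 1]) / 2 + 1              # samples at 500 Hz
    expect_true(all(len >= res$min_run_samples))
    expect_true(all(res$significant ==
                      erpfield:::filter_runs(res$p_values < res$alpha,
                                             res$min_run_samples)))
  }
})
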