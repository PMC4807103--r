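make_paired <- function(n = 15, ch = 32, s = 40, seed = 17, effect = 0) {
  set.seed(seed)
  A <- array(rnorm(n * ch * s), c(n, ch, s))
  B <- array(rnorm(n * ch * s), c(n, ch, s))
  if (effect != 0) A[, 1:6, 10:30] <- A[, 1:6, 10:30] + effect
  list(A = erps_from_array(A, window = c(-20, 58)),
       B = erps_from_array(B, window = c(-20, 58)))
}

test_that("identical conditions give p = 1 everywhere (zero-variance rule)", {
  d <- make_paired(n = 6)
  tt <- pointwise_paired_t(d$A, d$A)
  expect_true(all(tt$p == 1))
  expect_true(all(is.na(tt$t)))
})

test_that("paired t matches t.test and flips sign with the contrast", {
  d <- make_paired(n = 10)
  tt <- pointwise_paired_t(d$A, d$B)
  expect_equal(tt$df, 9)
  set.seed(19)
  for (i in 1:5) {
    ch <- sample(32, 1); s <- sample(40, 1)
    a <- vapply(d$A, function(e) e$data[ch, s], numeric(1))
    b <- vapply(d$B, function(e) e$data[ch, s], numeric(1))
    ref <- stats::t.test(a, b, paired = TRUE)
    expect_equal(tt$t[ch, s], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(tt$p[ch, s], ref$p.value, tolerance = 1e-10)
  }
  rev <- pointwise_paired_t(d$B, d$A)
  expect_equal(rev$t, -tt$t, tolerance = 1e-12)
})

test_that("p crosses .05 exactly at the critical t with 14 df", {
  # n = 15 subjects: two-tailed critical value 2.1448
  expect_lt(2 * stats::pt(-2.146, 14), 0.05)
  expect_gt(2 * stats::pt(-2.144, 14), 0.05)
})

test_that("temporal criterion clears runs of 9 and keeps runs of 10", {
  m <- matrix(FALSE, 2, 40)
  m[1, 5:13] <- TRUE                      # 9 samples
  m[2, 5:14] <- TRUE                      # 10 samples
  out <- apply_temporal_criterion(m, 10)
  expect_false(any(out[1, ]))
  expect_equal(out[2, ], m[2, ])
  all_true <- matrix(TRUE, 3, 15)
  expect_equal(apply_temporal_criterion(all_true, 10), all_true)
})

test_that("spatial criterion needs five contiguous electrodes in one cluster", {
  mon <- fx_mon110()
  cl <- names(which.max(table(mon$clusters)))
  mask <- function(idx) {
    m <- matrix(FALSE, 110, 1)
    m[idx, 1] <- TRUE
    m
  }
  four <- connected_subset(mon, cl, 4)
  five <- connected_subset(mon, cl, 5)
  expect_false(any(apply_spatial_criterion(mask(four), mon, 5)))
  out5 <- apply_spatial_criterion(mask(five), mon, 5)
  expect_equal(which(out5[, 1]), sort(five))
  # six electrodes split 3 + 3 across two clusters are cleared
  cl2 <- setdiff(levels(mon$clusters), cl)[1]
  split6 <- c(connected_subset(mon, cl, 3), connected_subset(mon, cl2, 3))
  expect_false(any(apply_spatial_criterion(mask(split6), mon, 5)))
})

test_that("criteria filters only ever remove significance", {
  mon <- fx_mon32()
  set.seed(23)
  for (rep in 1:10) {
    m <- matrix(runif(32 * 30) < 0.3, 32, 30)
    t_f <- apply_temporal_criterion(m, 5)
    s_f <- apply_spatial_criterion(m, mon, 3)
    expect_true(all(m[t_f]))                     # filtered subset of raw
    expect_true(all(m[s_f]))
  }
})

test_that("waveform analysis wires t-tests and both criteria together", {
  d <- make_paired(n = 12, effect = 1.5, seed = 29)
  mon <- fx_mon32()
  wf <- waveform_analysis(d$A, d$B, mon, min_run_samples = 5,
                          min_electrodes = 3)
  expect_true(all(wf$p_values[wf$significant] < 0.05))
  expect_true(all(wf$significant_raw[wf$significant]))
  expect_gt(sum(wf$significant), 0)              # injected effect found
  iv <- export_significant_intervals(wf, d$A[[1]]$times, mon)
  expect_true(all(iv$end_ms >= iv$start_ms))
  expect_true(all(abs(iv$peak_t) >= t_critical(0.05, 11) - 1e-9))
})
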