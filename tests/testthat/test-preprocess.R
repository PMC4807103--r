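test_that("band-pass keeps 10 Hz, removes DC and attenuates out-of-band", {
  fs <- 500
  t <- seq(0, 4, by = 1 / fs)
  mid <- seq(round(length(t) * 0.25), round(length(t) * 0.75))
  gain_at <- function(f) {
    y <- bandpass(sin(2 * pi * f * t), fs)
    max(abs(y[mid]))
  }
  expect_gt(gain_at(10), 0.95)                   # passband
  expect_lt(gain_at(50), 0.10)                   # >= 90% reduction
  expect_lt(gain_at(0.1), 10^(-20 / 20))         # >= 20 dB down
  expect_lt(gain_at(60), 10^(-20 / 20))
  dc <- bandpass(rep(5, length(t)), fs)
  expect_lt(max(abs(dc)), 1e-6)
  expect_error(bandpass(rnorm(100), 50, high_hz = 30), "Nyquist")
})

test_that("zero-phase response matches forward-backward IIR filtering", {
  set.seed(2)
  fs <- 500
  x <- rnorm(3000)
  y <- bandpass(x, fs)
  flt <- signal::butter(2, c(1, 30) / (fs / 2), "pass")
  y2 <- signal::filtfilt(flt, x)
  mid <- 800:2200
  expect_lt(max(abs(y[mid] - y2[mid])) / max(abs(y2[mid])), 5e-3)
})

test_that("average reference zeroes the channel mean and keeps differences", {
  expect_equal(rereference_average(c(5, 5, 5)), c(0, 0, 0))
  expect_equal(rereference_average(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(3)
  m <- matrix(rnorm(40), 8)
  r <- rereference_average(m)
  expect_lt(max(abs(colMeans(r))), 1e-12)
  expect_equal(r[3, ] - r[5, ], m[3, ] - m[5, ])          # differences kept
  expect_equal(rereference_average(r), r)                 # idempotent
  expect_error(rereference_average(5))
})

test_that("amplitude rejection follows the 65 uV criterion exactly", {
  mk <- function(peaks) {
    dat <- array(0, c(4, 51, length(peaks)))
    for (i in seq_along(peaks)) dat[2, 10, i] <- peaks[i]
    epoch_set(dat, 500, c(-20, 80))
  }
  ep <- reject_amplitude(mk(c(64.9, 70, 0, -70)), 65)
  expect_equal(ep$trial_flags,
               c("accepted", "amplitude_rejected", "accepted",
                 "amplitude_rejected"))
  # previously excluded trials keep their flags
  ep2 <- mk(c(70, 70))
  ep2$trial_flags[1] <- "emg_excluded"
  expect_equal(reject_amplitude(ep2, 65)$trial_flags,
               c("emg_excluded", "amplitude_rejected"))
})

test_that("rejection is monotone in the threshold", {
  set.seed(5)
  dat <- array(rnorm(6 * 40 * 30, sd = 30), c(6, 40, 30))
  ep <- epoch_set(dat, 500, c(-20, 58))
  n_rej <- vapply(c(20, 40, 65, 90, 120), function(th)
    sum(reject_amplitude(ep, th)$trial_flags == "amplitude_rejected"),
    numeric(1))
  expect_true(all(diff(n_rej) <= 0))
})

test_that("the 80-trial floor separates usable from unusable sessions", {
  mk <- function(n_acc, n_tot = 100) {
    ep <- epoch_set(array(0, c(3, 26, n_tot)), 500, c(-10, 40))
    ep$trial_flags[seq_len(n_tot - n_acc)] <- "amplitude_rejected"
    ep
  }
  expect_false(enforce_trial_floor(mk(79))$usable)
  expect_true(enforce_trial_floor(mk(80))$usable)
  expect_equal(enforce_trial_floor(mk(85))$n_accepted, 85)
})

test_that("trial and subject averaging equal the brute-force mean", {
  set.seed(7)
  dat <- array(rnorm(5 * 20 * 6), c(5, 20, 6))
  ep <- epoch_set(dat, 500, c(-10, 28))
  # identical trials average to the trial
  ep_same <- epoch_set(array(rep(dat[, , 1], 3), c(5, 20, 3)), 500,
                       c(-10, 28))
  expect_equal(average_trials(ep_same)$data, dat[, , 1])
  # +v and -v cancel
  ep_pm <- epoch_set(array(c(dat[, , 1], -dat[, , 1]), c(5, 20, 2)), 500,
                     c(-10, 28))
  expect_equal(max(abs(average_trials(ep_pm)$data)), 0)
  # independent summation oracle at both levels
  oracle <- dat[, , 1] * 0
  for (k in 1:6) oracle <- oracle + dat[, , k]
  expect_equal(average_trials(ep)$data, oracle / 6, tolerance = 1e-12)
  erps <- erps_from_array(aperm(dat, c(3, 1, 2)), window = c(-10, 28))
  expect_equal(average_subjects(erps)$data, oracle / 6, tolerance = 1e-12)
  expect_equal(average_subjects(erps)$n_trials, 6)
  expect_error(average_subjects(list()), "no subject")
})

test_that("the preprocessing chain runs in protocol order and logs it", {
  d <- suppressWarnings(sim_design(
    n_subjects = 1, n_trials_per_condition = 12, n_channels = 24,
    epoch_window = c(-100, 300), noise_sd = 10, artifact_rate = 0.1,
    artifact_amplitude = 120, emg_exclusion_rate = 0, error_trial_rate = 0,
    seed = 3))
  ex <- simulate_experiment(d, head = fx_head())
  pp <- preprocess_subject(ex$subjects[[1]]$A, ex$montage,
                           bad_channels = 3, min_trials = 2)
  steps <- c("bandpass", "average reference", "amplitude rejection",
             "trial floor", "interpolation", "averaged")
  hits <- vapply(steps, function(s) grep(s, pp$log)[1], numeric(1))
  expect_false(anyNA(hits))
  expect_true(all(diff(hits) > 0))              # protocol order enforced
  # resulting ERP is average-referenced
  expect_lt(max(abs(colMeans(pp$erp$data))), 1e-9)
  # a floor above the trial count marks the session unusable
  pp2 <- preprocess_subject(ex$subjects[[1]]$A, ex$montage, min_trials = 80)
  expect_false(pp2$usable)
  expect_null(pp2$erp)
})
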