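# Small designs keep the generator tests fast; the epoch window is shortened
# but always spans cue onset.

tiny_design <- function(..., components = list()) {
  suppressWarnings(sim_design(
    n_subjects = 2, n_trials_per_condition = 4, n_channels = 24,
    epoch_window = c(-100, 300), components = components,
    artifact_rate = 0, emg_exclusion_rate = 0, error_trial_rate = 0,
    subject_gain_sd = 0, ...))
}

comp_at <- function(amplitude, gains = c(1, 1), locations = NULL) {
  source_component(location = c(0.1290, 0, 0.6451), orientation = c(0, 0, 1),
                   peak_ms = 150, fwhm_ms = 60, amplitude = amplitude,
                   condition_gains = gains, condition_locations = locations)
}

test_that("zero sources and zero noise give exactly zero voltages", {
  ex <- simulate_experiment(tiny_design(noise_sd = 0), head = fx_head())
  expect_identical(max(abs(ex$subjects[[1]]$A$data)), 0)
  expect_identical(max(abs(ex$subjects[[2]]$B$data)), 0)
})

test_that("sensor data are linear in component amplitude", {
  d1 <- tiny_design(noise_sd = 0, components = list(comp_at(10)))
  d2 <- tiny_design(noise_sd = 0, components = list(comp_at(20)))
  ex1 <- simulate_experiment(d1, head = fx_head())
  ex2 <- simulate_experiment(d2, montage = ex1$montage, head = fx_head())
  expect_equal(ex2$subjects[[1]]$A$data, 2 * ex1$subjects[[1]]$A$data,
               tolerance = 1e-12)
})

test_that("condition gains scale GFP but leave topography identical", {
  d <- tiny_design(noise_sd = 0, components = list(comp_at(10, c(1, 2))))
  ex <- simulate_experiment(d, head = fx_head())
  gA <- average_trials(ex$subjects[[1]]$A)
  gB <- average_trials(ex$subjects[[1]]$B)
  pk <- which.min(abs(gA$times - 150))
  expect_gt(gfp(gB$data)[pk], gfp(gA$data)[pk] * 1.9)
  expect_lt(diss(gA$data[, pk], gB$data[, pk]), 1e-10)
})

test_that("a displaced generator produces topographic dissimilarity", {
  locs <- list(A = c(0.1290, 0.3871, 0.3871), B = c(0.1290, -0.3871, 0.3871))
  d <- tiny_design(noise_sd = 0,
                   components = list(source_component(
                     location = locs$A, orientation = "radial",
                     peak_ms = 150, fwhm_ms = 60, amplitude = 10,
                     condition_locations = locs)))
  ex <- simulate_experiment(d, head = fx_head())
  gA <- average_trials(ex$subjects[[1]]$A)
  gB <- average_trials(ex$subjects[[1]]$B)
  pk <- which.min(abs(gA$times - 150))
  expect_gt(diss(gA$data[, pk], gB$data[, pk]), 0.5)
  # strength was equalized: the effect is configuration-only
  expect_equal(gfp(gA$data)[pk], gfp(gB$data)[pk], tolerance = 1e-6)
})

test_that("injected artifacts are recorded and recovered by rejection", {
  d <- suppressWarnings(sim_design(
    n_subjects = 1, n_trials_per_condition = 100, n_channels = 24,
    epoch_window = c(-100, 300), components = list(),
    noise_sd = 10, artifact_rate = 0.1, artifact_amplitude = 120,
    emg_exclusion_rate = 0, error_trial_rate = 0, seed = 9))
  ex <- simulate_experiment(d, head = fx_head())
  ep <- ex$subjects[[1]]$A
  truth <- ex$ground_truth$artifact_trials[["subject01_A"]]
  expect_gt(length(truth), 0)
  flagged <- which(reject_amplitude(ep, 65)$trial_flags ==
                     "amplitude_rejected")
  expect_gte(sum(truth %in% flagged), ceiling(0.95 * length(truth)))
})

test_that("simulation is bit-for-bit reproducible for a fixed seed", {
  d <- tiny_design(noise_sd = 8, components = list(comp_at(10)), seed = 21)
  ex1 <- simulate_experiment(d, head = fx_head())
  ex2 <- simulate_experiment(d, montage = ex1$montage, head = fx_head())
  expect_identical(ex1$subjects, ex2$subjects)
  ex3 <- simulate_experiment(tiny_design(noise_sd = 8,
                                         components = list(comp_at(10)),
                                         seed = 22),
                             montage = ex1$montage, head = fx_head())
  expect_false(identical(ex1$subjects, ex3$subjects))
})

test_that("invalid designs are rejected", {
  expect_error(simulate_experiment(
    tiny_design(components = list(source_component(
      location = c(0, 0, 0.9), orientation = "radial", peak_ms = 100,
      fwhm_ms = 50, amplitude = 1))), head = fx_head()),
    "outside the brain sphere")
  expect_error(sim_design(artifact_rate = 0.1, artifact_amplitude = 60),
               "65")
  expect_warning(sim_design(n_trials_per_condition = 50),
                 "fewer than 80")
})

test_that("ground truth JSON lists the injected effects", {
  d <- tiny_design(noise_sd = 5, components = list(comp_at(10, c(1, 1.6))))
  ex <- simulate_experiment(d, head = fx_head())
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(ex, path)
  gt <- jsonlite::read_json(path, simplifyVector = FALSE)
  expect_equal(unlist(gt$components[[1]]$condition_gains), c(1, 1.6))
  expect_equal(gt$seed, d$seed)
})
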