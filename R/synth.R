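#' Define a dipolar source component
#'
#' A neural generator for the synthetic ERP experiment: a current dipole
#' inside the brain sphere with a Gaussian-windowed time course.  Condition
#' effects are expressed either as per-condition amplitude multipliers
#' (strength effects, which modulate Global Field Power but not topography)
#' or as per-condition locations (topography effects, which change the scalp
#' map configuration).
#'
#' @param location 3-vector, dipole position in normalized head units,
#'   strictly inside the brain sphere.
#' @param orientation 3-vector (normalized internally), or the string
#'   `"radial"` for a radially oriented dipole at its (per-condition)
#'   location.
#' @param peak_ms latency of the Gaussian peak, ms after cue onset.
#' @param fwhm_ms full width at half maximum of the Gaussian envelope, ms.
#' @param amplitude peak dipole moment, nA·m-scale units (>= 0).
#' @param condition_gains per-condition amplitude multipliers.
#' @param condition_locations optional list of per-condition locations
#'   overriding `location` (topography effect).
#' @param equalize_gfp when the component has per-condition locations,
#'   rescale each condition's scalp map to the Global Field Power of the
#'   first condition's map (default TRUE), so a displaced generator changes
#'   the field configuration but not its strength — a pure topography
#'   effect.
#' @param active_window optional ms pair outside which the time course is
#'   clipped to zero.
#' @return object of class `source_component`.
#' @export
source_component <- function(location, orientation = "radial",
                             peak_ms, fwhm_ms, amplitude,
                             condition_gains = c(1, 1),
                             condition_locations = NULL,
                             equalize_gfp = TRUE,
                             active_window = NULL) {
  stopifnot(length(location) == 3, amplitude >= 0, fwhm_ms > 0)
  if (!identical(orientation, "radial")) {
    stopifnot(length(orientation) == 3)
    nrm <- sqrt(sum(orientation^2))
    if (nrm == 0) stop("orientation must be a non-zero vector")
    orientation <- orientation / nrm
  }
  structure(
    list(location = as.numeric(location), orientation = orientation,
         peak_ms = peak_ms, fwhm_ms = fwhm_ms, amplitude = amplitude,
         condition_gains = condition_gains,
         condition_locations = condition_locations,
         equalize_gfp = equalize_gfp,
         active_window = active_window),
    class = "source_component")
}

component_location <- function(comp, cond_idx) {
  if (!is.null(comp$condition_locations))
    as.numeric(comp$condition_locations[[cond_idx]])
  else comp$location
}

component_orientation <- function(comp, cond_idx) {
  if (identical(comp$orientation, "radial")) {
    loc <- component_location(comp, cond_idx)
    loc / sqrt(sum(loc^2))
  } else comp$orientation
}

component_timecourse <- function(comp, times) {
  w <- exp(-4 * log(2) * (times - comp$peak_ms)^2 / comp$fwhm_ms^2)
  if (!is.null(comp$active_window))
    w[times < comp$active_window[1] | times > comp$active_window[2]] <- 0
  comp$amplitude * w
}

#' Default source configuration of the two-session simulation
#'
#' Three generators emulating a cue-elicited preparatory ERP in a two-session
#' (overt vs covert) Go/NoGo experiment: (1) a posterior visual response
#' common to both sessions; (2) a central preparatory component whose
#' strength is 1.6x larger in session A, peaking at 350 ms (a pure Global
#' Field Power effect around 300--400 ms); (3) a late component whose
#' generator sits in left sensorimotor cortex in session A but in right
#' inferior-frontal cortex in session B, active around 430--480 ms (a pure
#' topography effect).
#'
#' Locations sit on solution points of the default ~1000-point source grid
#' so that simulated ground truth is exactly representable in the default
#' source space (the usual convention for source-recovery simulations).
#'
#' @return list of [source_component()] objects.
#' @export
default_components <- function() {
  list(
    visual = source_component(
      location = c(-0.5161, 0, 0.2580), orientation = "radial",
      peak_ms = 120, fwhm_ms = 80, amplitude = 25,
      condition_gains = c(1, 1)),
    preparatory = source_component(
      location = c(0.1290, 0, 0.6451), orientation = c(0, 0, 1),
      peak_ms = 350, fwhm_ms = 90, amplitude = 20,
      condition_gains = c(1.6, 1)),
    late_shift = source_component(
      location = c(0.1290, 0.3871, 0.3871), orientation = "radial",
      peak_ms = 455, fwhm_ms = 45, amplitude = 18,
      condition_gains = c(1, 1),
      condition_locations = list(A = c(0.1290, 0.3871, 0.3871),
                                 B = c(0.1290, -0.3871, 0.3871))))
}

#' Specify a synthetic two-session ERP experiment
#'
#' Bundles every parameter of the synthetic data generator.  Defaults
#' emulate the recording protocol of a two-session preparatory-ERP study:
#' 15 subjects, 110 channels at 500 Hz, epochs −200..1000 ms around the cue,
#' ~100 trials per condition with artifact and exclusion rates that leave
#' the 80-trial floor attainable.
#'
#' @param n_subjects number of subjects.
#' @param n_trials_per_condition trials recorded per condition.
#' @param n_channels electrodes in the montage.
#' @param sampling_rate Hz.
#' @param epoch_window ms pair spanning cue onset.
#' @param components list of [source_component()]; default
#'   [default_components()].
#' @param noise_sd per-channel, per-sample standard deviation of the
#'   additive sensor noise in microvolts (temporally white; its 1–30 Hz
#'   band-limited counterpart after filtering is about a third of this).
#' @param noise_spatial_corr correlation of the noise between neighbouring
#'   electrodes (0..1); an exponential spatial covariance over
#'   inter-electrode distance is scaled to reach this value at the median
#'   nearest-neighbour distance.
#' @param artifact_rate fraction of trials receiving an injected
#'   high-amplitude artifact transient.
#' @param artifact_amplitude peak amplitude of injected artifacts in
#'   microvolts (must exceed the 65 μV rejection criterion when
#'   `artifact_rate > 0`).
#' @param subject_gain_sd log-normal standard deviation of the per-subject
#'   global amplitude gain.
#' @param emg_exclusion_rate fraction of trials pre-flagged as EMG-excluded.
#' @param error_trial_rate fraction of trials pre-flagged as error trials.
#' @param seed master integer seed; every random substream derives from it.
#' @return object of class `sim_design`; carries a `floor_risk` flag when
#'   the expected number of accepted trials falls below 80.
#' @export
sim_design <- function(n_subjects = 15, n_trials_per_condition = 100,
                       n_channels = 110, sampling_rate = 500,
                       epoch_window = c(-200, 1000),
                       components = default_components(),
                       noise_sd = 15, noise_spatial_corr = 0.6,
                       artifact_rate = 0.05, artifact_amplitude = 120,
                       subject_gain_sd = 0.2,
                       emg_exclusion_rate = 0.02, error_trial_rate = 0.02,
                       seed = 1) {
  stopifnot(n_subjects >= 1, n_trials_per_condition >= 1, n_channels >= 16,
            epoch_window[1] < 0, epoch_window[2] > 0,
            noise_sd >= 0, noise_spatial_corr >= 0, noise_spatial_corr < 1,
            artifact_rate >= 0, artifact_rate < 1, subject_gain_sd >= 0)
  if (artifact_rate > 0 && artifact_amplitude <= 65)
    stop("artifact_amplitude must exceed the 65 uV rejection criterion")
  expected_accepted <- n_trials_per_condition *
    (1 - artifact_rate - emg_exclusion_rate - error_trial_rate)
  floor_risk <- expected_accepted < 80
  if (floor_risk)
    warning("design expects fewer than 80 accepted trials per condition; ",
            "the trial-count floor may reject subjects")
  structure(
    list(n_subjects = n_subjects,
         n_trials_per_condition = n_trials_per_condition,
         n_channels = n_channels, sampling_rate = sampling_rate,
         epoch_window = epoch_window, components = components,
         noise_sd = noise_sd, noise_spatial_corr = noise_spatial_corr,
         artifact_rate = artifact_rate,
         artifact_amplitude = artifact_amplitude,
         subject_gain_sd = subject_gain_sd,
         emg_exclusion_rate = emg_exclusion_rate,
         error_trial_rate = error_trial_rate,
         seed = as.integer(seed), floor_risk = floor_risk),
    class = "sim_design")
}

#' Simulate a two-session multi-subject ERP experiment
#'
#' Projects every source component through the spherical-head forward model,
#' applies condition gains (strength effects), per-condition source
#' locations (topography effects) and per-subject log-normal gains, adds
#' spatially correlated Gaussian sensor noise, injects artifact transients
#' into a random subset of trials and pre-flags EMG/error exclusions.  The
#' whole experiment is a deterministic function of the design's master seed:
#' subject s / condition c uses random substream
#' `substream_seed(seed, s, c)`.
#'
#' @param design a [sim_design()].
#' @param montage optional [build_montage()]; built from the design if
#'   omitted.
#' @param head optional [head_model()]; default three-shell model.
#' @return object of class `simulated_experiment`: list with `subjects`
#'   (per subject, a list of `epoch_set`s named by condition), `montage`,
#'   `head`, `design`, `conditions`, and `ground_truth` (true component
#'   parameters per condition, per-subject gains, and the indices of every
#'   injected artifact / exclusion flag).
#' @export
simulate_experiment <- function(design, montage = NULL, head = NULL) {
  stopifnot(inherits(design, "sim_design"))
  montage <- montage %||% build_montage(design$n_channels)
  head <- head %||% head_model()
  conditions <- c("A", "B")
  times <- seq(design$epoch_window[1], design$epoch_window[2],
               by = 1000 / design$sampling_rate)
  n_s <- length(times)
  n_ch <- length(montage$labels)
  n_tr <- design$n_trials_per_condition

  for (comp in design$components) {
    for (ci in seq_along(conditions)) {
      loc <- component_location(comp, ci)
      if (sqrt(sum(loc^2)) >= head$brain_radius)
        stop("source component location outside the brain sphere")
    }
  }

  # condition-specific noiseless signal templates (channels x samples),
  # unit subject gain
  signal <- lapply(seq_along(conditions), function(ci) {
    sig <- matrix(0, n_ch, n_s)
    for (comp in design$components) {
      loc <- component_location(comp, ci)
      ori <- component_orientation(comp, ci)
      map <- dipole_potentials(head, loc, ori, montage$positions)[, 1]
      if (!is.null(comp$condition_locations) && comp$equalize_gfp) {
        # pure topography effect: match the scalp strength of condition 1
        ref <- dipole_potentials(head, component_location(comp, 1L),
                                 component_orientation(comp, 1L),
                                 montage$positions)[, 1]
        map <- map * gfp(ref) / gfp(map)
      }
      tc <- component_timecourse(comp, times) * comp$condition_gains[ci]
      sig <- sig + outer(map, tc)
    }
    sig
  })
  names(signal) <- conditions

  noise_chol <- if (design$noise_sd > 0 && design$noise_spatial_corr > 0) {
    D <- as.matrix(stats::dist(montage$positions))
    nn <- apply(D + diag(Inf, n_ch), 1, min)
    len <- stats::median(nn) / (-log(design$noise_spatial_corr))
    chol(exp(-D / len))
  } else NULL

  subject_gains <- vapply(seq_len(design$n_subjects), function(s) {
    with_seed(substream_seed(design$seed, s, 0L),
              exp(stats::rnorm(1, 0, design$subject_gain_sd)))
  }, numeric(1))

  gt_artifacts <- list()
  gt_excluded <- list()
  subjects <- vector("list", design$n_subjects)
  for (s in seq_len(design$n_subjects)) {
    per_cond <- vector("list", length(conditions))
    names(per_cond) <- conditions
    for (ci in seq_along(conditions)) {
      res <- with_seed(substream_seed(design$seed, s, ci), {
        dat <- array(0, dim = c(n_ch, n_s, n_tr))
        base <- signal[[ci]] * subject_gains[s]
        for (tr in seq_len(n_tr)) {
          noise <- matrix(stats::rnorm(n_ch * n_s, 0, design$noise_sd),
                          n_ch, n_s)
          if (!is.null(noise_chol)) noise <- crossprod(noise_chol, noise)
          dat[, , tr] <- base + noise
        }
        flags <- rep("accepted", n_tr)
        n_excl <- stats::rbinom(1, n_tr,
                                design$emg_exclusion_rate +
                                  design$error_trial_rate)
        excl <- sort(sample.int(n_tr, n_excl))
        if (n_excl > 0) {
          kinds <- sample(c("emg_excluded", "error_trial"), n_excl,
                          replace = TRUE)
          flags[excl] <- kinds
        }
        art <- which(stats::runif(n_tr) < design$artifact_rate)
        for (tr in art) {
          ch <- sample.int(n_ch, 1)
          t0 <- sample.int(n_s - 25L, 1)
          idx <- t0:(t0 + 24L)                      # 50 ms half-sine burst
          pulse <- sin(seq(0, pi, length.out = 25L)) *
            design$artifact_amplitude * sample(c(-1, 1), 1)
          dat[ch, idx, tr] <- dat[ch, idx, tr] + pulse
        }
        list(dat = dat, flags = flags, art = art, excl = excl)
      })
      per_cond[[ci]] <- epoch_set(res$dat, design$sampling_rate,
                                  design$epoch_window, res$flags,
                                  montage_ref = n_ch)
      key <- sprintf("subject%02d_%s", s, conditions[ci])
      gt_artifacts[[key]] <- res$art
      gt_excluded[[key]] <- res$excl
    }
    subjects[[s]] <- per_cond
  }

  gt_components <- lapply(design$components, function(comp) {
    list(peak_ms = comp$peak_ms, fwhm_ms = comp$fwhm_ms,
         amplitude = comp$amplitude,
         condition_gains = comp$condition_gains,
         locations = lapply(seq_along(conditions),
                            function(ci) component_location(comp, ci)),
         orientations = lapply(seq_along(conditions),
                               function(ci) component_orientation(comp, ci)))
  })

  structure(
    list(subjects = subjects, conditions = conditions, montage = montage,
         head = head, design = design,
         ground_truth = list(components = gt_components,
                             subject_gains = subject_gains,
                             artifact_trials = gt_artifacts,
                             excluded_trials = gt_excluded,
                             seed = design$seed)),
    class = "simulated_experiment")
}

#' Write the simulation ground truth as JSON
#'
#' @param experiment a [simulate_experiment()] result.
#' @param path output JSON path.
#' @export
write_ground_truth <- function(experiment, path) {
  jsonlite::write_json(experiment$ground_truth, path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.simulated_experiment <- function(x, ...) {
  cat(sprintf(
    "<simulated_experiment> %d subjects x %s, %d channels, seed %d\n",
    length(x$subjects), paste(x$conditions, collapse = "/"),
    length(x$montage$labels), x$design$seed))
  invisible(x)
}
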