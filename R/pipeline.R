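#' Pipeline configuration with protocol defaults
#'
#' Collects every stage parameter of the analysis chain.  The defaults are
#' the recording/analysis protocol this package targets: 500 Hz sampling,
#' 1--30 Hz band-pass, epochs −200..1000 ms, 65 μV rejection, 80-trial
#' floor, 110 channels, alpha = .05, 20 ms persistence, 5 contiguous
#' electrodes within nine clusters, 1000 permutations, and a 10-point
#' cluster-extent threshold for the voxel-wise source contrast.  Any
#' override is recorded in the `overrides` field and echoed in the report.
#'
#' @param ... named overrides of any default listed above.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    sampling_rate = 500, low_hz = 1, high_hz = 30,
    epoch_window = c(-200, 1000), reject_uv = 65, min_trials = 80,
    n_channels = 110, n_subjects = 15, n_trials = 100,
    alpha = 0.05, persistence_ms = 20,
    min_electrodes = 5, n_permutations = 1000, cluster_min = 10,
    n_source_points = 1000, lambda = "gcv",
    source_method = "sloreta",  # standardized mapping; "laura" for raw
                                # current-density contrasts
    bad_channels = integer(0),
    source_windows = NULL,    # NULL: take windows from the TANOVA result
    seed = 1, out_dir = NULL)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop("unknown pipeline parameter(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, overrides)
  cfg$overrides <- names(overrides)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are [pipeline_config()] parameters.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' Orchestrates synthesis (or ingestion) → preprocessing → mass-univariate
#' waveform statistics → GFP randomization test → TANOVA → source estimation
#' on the TANOVA windows → voxel-wise contrast, and assembles a structured
#' report.  Fully reproducible: the report is a deterministic function of
#' the configuration (including its seed).
#'
#' @param config a [pipeline_config()].
#' @param design optional [sim_design()]; by default one is built from the
#'   configuration (same channels, rate, window and seed).
#' @param experiment optional pre-simulated [simulate_experiment()] (takes
#'   precedence over `design`).
#' @return object of class `pipeline_report` (also written as JSON and
#'   human-readable text when `config$out_dir` is set): effective
#'   parameters, per-subject preprocessing summary, significant waveform
#'   intervals, GFP and TANOVA windows, and source clusters per TANOVA
#'   window.
#' @export
run_pipeline <- function(config = pipeline_config(), design = NULL,
                         experiment = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  if (is.null(experiment)) {
    design <- design %||% sim_design(
      n_subjects = config$n_subjects,
      n_trials_per_condition = config$n_trials,
      n_channels = config$n_channels, sampling_rate = config$sampling_rate,
      epoch_window = config$epoch_window, seed = config$seed)
    experiment <- simulate_experiment(design)
  }
  montage <- experiment$montage
  head <- experiment$head
  min_run <- min_run_samples(config$persistence_ms, config$sampling_rate)

  # preprocessing -----------------------------------------------------
  conditions <- experiment$conditions
  erps <- stats::setNames(vector("list", length(conditions)), conditions)
  prep_summary <- list()
  usable <- rep(TRUE, length(experiment$subjects))
  for (s in seq_along(experiment$subjects)) {
    for (cond in conditions) {
      pp <- preprocess_subject(
        experiment$subjects[[s]][[cond]], montage,
        bad_channels = config$bad_channels, low_hz = config$low_hz,
        high_hz = config$high_hz, reject_uv = config$reject_uv,
        min_trials = config$min_trials)
      prep_summary[[sprintf("subject%02d_%s", s, cond)]] <-
        list(usable = pp$usable, n_accepted = pp$n_accepted)
      if (!pp$usable) usable[s] <- FALSE
      erps[[cond]][s] <- list(pp$erp)   # keep NULL slots without shifting
    }
  }
  if (!any(usable)) stop("pipeline aborted at preprocessing: no usable subject")
  for (cond in conditions) erps[[cond]] <- erps[[cond]][usable]

  # waveform statistics ------------------------------------------------
  wf <- waveform_analysis(erps[[1]], erps[[2]], montage,
                          alpha = config$alpha, min_run_samples = min_run,
                          min_electrodes = config$min_electrodes)
  times <- erps[[1]][[1]]$times
  wf_intervals <- export_significant_intervals(wf, times, montage)

  # global field statistics --------------------------------------------
  gfp_res <- gfp_randomization_test(
    erps[[1]], erps[[2]], n_perm = config$n_permutations,
    alpha = config$alpha, min_run_samples = min_run,
    seed = substream_seed(config$seed, 11L))
  tan_res <- tanova(
    erps[[1]], erps[[2]], n_perm = config$n_permutations,
    alpha = config$alpha, min_run_samples = min_run,
    seed = substream_seed(config$seed, 12L))

  # source analysis on the TANOVA windows ------------------------------
  windows <- config$source_windows
  if (is.null(windows)) {
    w <- tan_res$significant_windows
    windows <- lapply(seq_len(nrow(w)), function(r) w[r, ])
  }
  grid <- NULL
  source_results <- list()
  if (length(windows)) {
    grid <- build_source_grid(head, n_points = config$n_source_points)
    lf <- compute_lead_field(grid, montage, head)
    inv <- if (config$source_method == "sloreta")
      build_sloreta_inverse(lf, grid, lambda = config$lambda)
    else build_laura_inverse(lf, grid, lambda = config$lambda)
    group1 <- average_subjects(erps[[1]])
    for (wi in seq_along(windows)) {
      win <- as.numeric(windows[[wi]])
      # one regularization per window, set on the group-average map
      lam <- apply_inverse(
        inv, rowMeans(group1$data[, times >= win[1] & times <= win[2],
                                  drop = FALSE]))$lambda
      actA <- t(vapply(erps[[1]], estimate_window_activity,
                       numeric(grid$n_points), inv = inv, window_ms = win,
                       lambda = lam))
      actB <- t(vapply(erps[[2]], estimate_window_activity,
                       numeric(grid$n_points), inv = inv, window_ms = win,
                       lambda = lam))
      ct <- voxelwise_contrast(actA, actB, grid, alpha = config$alpha,
                               cluster_min = config$cluster_min)
      source_results[[sprintf("window_%g_%g_ms", win[1], win[2])]] <-
        list(window_ms = win, lambda = lam, clusters = ct$clusters,
             contrast = ct)
    }
  }

  report <- structure(
    list(parameters = config[setdiff(names(config), "overrides")],
         overridden_parameters = config$overrides,
         n_subjects_usable = sum(usable),
         preprocessing = prep_summary,
         waveform_intervals = wf_intervals,
         gfp_windows = gfp_res$significant_windows,
         tanova_windows = tan_res$significant_windows,
         source_windows = lapply(source_results, function(sr)
           list(window_ms = sr$window_ms, lambda = sr$lambda,
                clusters = sr$clusters)),
         seed = config$seed,
         elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "pipeline_report")
  attr(report, "objects") <- list(waveform = wf, gfp = gfp_res,
                                  tanova = tan_res, grid = grid,
                                  sources = source_results, erps = erps,
                                  montage = montage)
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Write a pipeline report as JSON and human-readable text
#'
#' The JSON omits the wall-clock timing field so that reruns with the same
#' seed are byte-identical.
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  js <- unclass(report)
  js$elapsed_s <- NULL
  js$parameters$out_dir <- NULL    # machine-local path; keep reruns
                                   # byte-identical
  jsonlite::write_json(js, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  con <- file(file.path(dir, "report.txt"), "w")
  on.exit(close(con))
  writeLines(utils::capture.output(print(report)), con)
  invisible(dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("=== erpfield pipeline report ===\n")
  cat(sprintf("seed %d; %d usable subjects\n", x$seed, x$n_subjects_usable))
  cat(sprintf("waveform: %d significant electrode intervals\n",
              nrow(x$waveform_intervals)))
  pw <- function(w, name) {
    if (nrow(w) == 0) cat(sprintf("%s: no significant windows\n", name))
    else for (r in seq_len(nrow(w)))
      cat(sprintf("%s window: %g..%g ms\n", name, w[r, 1], w[r, 2]))
  }
  pw(x$gfp_windows, "GFP")
  pw(x$tanova_windows, "TANOVA")
  for (nm in names(x$source_windows)) {
    sw <- x$source_windows[[nm]]
    cat(sprintf("sources %g..%g ms (lambda %.3g): %d cluster(s)\n",
                sw$window_ms[1], sw$window_ms[2], sw$lambda,
                nrow(sw$clusters)))
    if (nrow(sw$clusters))
      print(sw$clusters, row.names = FALSE, digits = 3)
  }
  invisible(x)
}
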