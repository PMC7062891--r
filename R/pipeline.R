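#' Scenario presets for the three experiments
#'
#' Bundles the task, model, acquisition, phantom, noise and inference
#' settings of the three experiment designs:
#' \describe{
#'   \item{1}{randomly alternating reward levels, irregular targets;
#'     n = 35, TR 2.46 s, 3 mm voxels, 8 mm smoothing.  Effects are planted
#'     at the cue in the ventral-striatum region and during the foraging
#'     patch in the midbrain region.}
#'   \item{2}{regularly alternating (fully predictable) reward levels,
#'     irregular targets; n = 17, TR 2.85 s, 2 x 2 x 2.5 mm voxels, 6 mm
#'     smoothing.  The cue amplitude is 0 (a predictable cue carries no
#'     prediction error), the foraging-patch effect remains.}
#'   \item{3}{randomly alternating reward levels, regular targets
#'     (1250 ms); n = 20, otherwise as experiment 2.}
#' }
#'
#' @param experiment 1, 2 or 3.
#' @param n_subjects override the preset cohort size.
#' @param n_perm permutation samples for the corrected inference.
#' @param seed master seed; every stage derives its own stream from it.
#' @param effect planted group-level amplitude (signal units per unit
#'   regressor) of the high-reward condition; the low-reward condition gets
#'   `effect / 5`.
#' @return A `scenario_config` list understood by [run_scenario()].
#' @export
experiment_preset <- function(experiment, n_subjects = NULL, n_perm = 6000L,
                              seed = 1L, effect = 0.5) {
  if (!experiment %in% 1:3) stop_tdbold("experiment must be 1, 2 or 3")
  tr <- if (experiment == 1) 2.46 else 2.85
  voxel_size <- if (experiment == 1) c(3, 3, 3) else c(2, 2, 2.5)
  fwhm <- if (experiment == 1) 8 else 6
  n_def <- c(35L, 17L, 20L)[experiment]
  task <- task_config(
    target_mode = if (experiment == 3) "regular" else "irregular",
    alternation = if (experiment == 2) "regular" else "random_balanced",
    seed = derive_seed(seed, 11L))
  amp_low <- effect / 5
  amplitudes <- list(
    VTA_SN = list(patch_high = effect, patch_low = amp_low))
  if (experiment != 2)
    amplitudes$VS <- list(cue_high = effect, cue_low = amp_low)
  contrasts <- list(
    cue = list(weights = c(cue_high = 1, cue_low = -1),
               roi = "ventral_striatum", cdt_p = 0.01,
               expect_region = if (experiment != 2) "VS" else NULL),
    patch = list(weights = c(patch_high = 1, patch_low = -1),
                 roi = NULL, cdt_p = 0.001, expect_region = "VTA_SN"))
  structure(list(
    experiment = experiment,
    task = task,
    td = td_config(seed = derive_seed(seed, 13L)),
    hrf = hrf_spec(),
    tr = tr,
    fwhm = fwhm,
    voxel_size = voxel_size,
    drift_cutoff = 128,
    phantom_shape = c(20L, 24L, 18L),
    noise = noise_spec(),
    n_subjects = if (is.null(n_subjects)) n_def else as.integer(n_subjects),
    between_sd = 0.1,
    amplitudes = amplitudes,
    contrasts = contrasts,
    n_perm = as.integer(n_perm),
    connectivity = 18L,
    seed = as.integer(seed)
  ), class = "scenario_config")
}

stage_log <- function(verbose, ...) if (verbose) message("[tdbold] ", ...)

#' Run one experiment scenario end to end
#'
#' Executes schedule generation, TD model training and recording, design
#' construction, synthetic cohort simulation with spatial smoothing,
#' first-level AR(1) GLM fits, per-contrast second-level random-effects
#' analysis, and permutation-corrected inference, deterministically from the
#' scenario's master seed.  Artefacts are written under `out_dir` when
#' given.
#'
#' @param config an [experiment_preset()] (or compatible list).
#' @param out_dir optional output directory for the artefact files.
#' @param write_volumes also write each subject's 4-D NIfTI (off by default;
#'   the volumes are large and reproducible from the seed).
#' @param verbose log stage progress.
#' @return A `run_report`: the schedule, model curves and consistency
#'   summaries, design, per-contrast subject effect maps, group results,
#'   permutation nulls and cluster tables, plus paths of written artefacts.
#' @export
run_scenario <- function(config, out_dir = NULL, write_volumes = FALSE,
                         verbose = FALSE) {
  if (config$n_subjects < 1L)
    stop_tdbold("scenario needs at least one subject")
  paths <- character(0)
  emit <- function(name, writer) {
    if (is.null(out_dir)) return(NULL)
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- file.path(out_dir, name)
    writer(p)
    paths[[name]] <<- p
    p
  }

  stage_log(verbose, "stage 1/6: trial schedule")
  schedule <- generate_schedule(config$task)
  emit("events.tsv", function(p) write_events(schedule, p))

  stage_log(verbose, "stage 2/6: TD model")
  gen <- chain_generator(config$task, config$experiment, config$td)
  values <- train_values(gen, config$td)
  trace <- record_trace(values, gen, config$td)
  curves <- smooth_trace_to_curves(trace, config$task, config$hrf)
  consistency <- list(
    foraging = consistency_residual(trace, "patch"),
    cue_entry = consistency_residual(trace, "cue", at = "entry"))
  emit("curves.tsv", function(p) {
    df <- data.frame(time = curves$time,
                     delta_low = curves$low$delta,
                     delta_high = curves$high$delta,
                     reward_low = curves$low$reward,
                     reward_high = curves$high$reward)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  })

  stage_log(verbose, "stage 3/6: design matrix")
  n_scans <- ceiling(schedule$total_duration / config$tr)
  design <- build_block_design(schedule, config$tr, n_scans, config$hrf,
                               drift_cutoff = config$drift_cutoff)
  emit("design.tsv", function(p) write_design(design, p))

  stage_log(verbose, "stage 4/6: synthetic cohort (n = ", config$n_subjects, ")")
  phantom <- build_phantom(config$phantom_shape, config$voxel_size)
  cohort <- cohort_spec(config$n_subjects, config$between_sd,
                        seed = derive_seed(config$seed, 17L))
  contrast_maps <- lapply(config$contrasts, function(x) vector("list", 0))
  rho_hat <- numeric(config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    amp_i <- config$amplitudes
    k <- 0L
    for (rg in names(amp_i)) for (cn in names(amp_i[[rg]])) {
      k <- k + 1L
      dev <- with_seed(derive_seed(cohort$seed, 1000L * i + k),
                       stats::rnorm(1, sd = cohort$between_sd))
      amp_i[[rg]][[cn]] <- amp_i[[rg]][[cn]] + dev
    }
    series <- simulate_subject(phantom, design, config$noise, amp_i,
                               seed = derive_seed(cohort$seed, i),
                               subject = sprintf("sub-%02d", i))
    series <- gaussian_smooth(series, config$fwhm, phantom$voxel_size)
    if (write_volumes && !is.null(out_dir))
      emit(sprintf("sub-%02d_bold.nii.gz", i),
           function(p) write_volume(series, p))
    fit <- fit_first_level(series, design)
    rho_hat[i] <- fit$rho
    for (cn in names(config$contrasts)) {
      cm <- contrast_map(fit, config$contrasts[[cn]]$weights)
      contrast_maps[[cn]][[i]] <- cm$effect
    }
  }

  stage_log(verbose, "stage 5/6: second level")
  group <- lapply(contrast_maps, second_level)

  stage_log(verbose, "stage 6/6: permutation inference")
  inference <- list(); tables <- list()
  for (cn in names(config$contrasts)) {
    spec <- config$contrasts[[cn]]
    mask <- if (!is.null(spec$roi)) builtin_roi(spec$roi, phantom) else NULL
    null <- permutation_correct(contrast_maps[[cn]], mask = mask,
                                n_perm = config$n_perm, cdt_p = spec$cdt_p,
                                analysis_type = "one_sample",
                                connectivity = config$connectivity,
                                seed = derive_seed(config$seed, 23L + match(cn, names(config$contrasts))))
    inference[[cn]] <- null
    tables[[cn]] <- cluster_report(null, phantom)
    emit(paste0("clusters_", cn, ".tsv"),
         function(p) write_cluster_table(tables[[cn]], p))
  }

  report <- structure(list(
    config = config, schedule = schedule,
    td = list(values = values, consistency = consistency, curves = curves,
              converged = values$converged),
    design = design, phantom = phantom,
    rho_hat = rho_hat,
    contrast_maps = contrast_maps, group = group,
    inference = inference, cluster_tables = tables,
    paths = paths
  ), class = "run_report")
  emit("report.txt", function(p) {
    con <- file(p, "w"); on.exit(close(con))
    writeLines(format_report(report), con)
  })
  report
}

format_report <- function(report) {
  cfg <- report$config
  out <- c(
    sprintf("tdbold scenario report (experiment %d, seed %d)",
            cfg$experiment, cfg$seed),
    sprintf("subjects: %d  TR: %.3g s  smoothing: %g mm  n_perm: %d",
            cfg$n_subjects, cfg$tr, cfg$fwhm, cfg$n_perm),
    sprintf("schedule: %d trials, %.1f s", length(report$schedule$trials),
            report$schedule$total_duration),
    sprintf("TD foraging residual: mean delta %.4g (n = %d)",
            report$td$consistency$foraging$mean,
            report$td$consistency$foraging$n),
    sprintf("mean estimated AR(1) rho: %.3f", mean(report$rho_hat)))
  for (cn in names(report$cluster_tables)) {
    tb <- report$cluster_tables[[cn]]
    out <- c(out, sprintf("contrast %s: %d cluster(s)", cn, nrow(tb)))
    if (nrow(tb))
      out <- c(out, utils::capture.output(print(tb, row.names = FALSE)))
  }
  out
}

#' @export
print.run_report <- function(x, ...) {
  writeLines(format_report(x))
  invisible(x)
}

#' Between-experiment interaction analysis
#'
#' Two-sample second-level comparison of a named contrast between two
#' scenario runs (e.g. the cue effect in experiments 1 vs 2), with
#' group-label permutation correction.
#'
#' @param report_a,report_b [run_scenario()] reports sharing grid and
#'   contrast definitions.
#' @param contrast contrast name present in both reports.
#' @param n_perm,cdt_p,seed inference settings.
#' @return List with the `group_result`, the `permutation_null` and the
#'   cluster `table`.
#' @export
compare_experiments <- function(report_a, report_b, contrast,
                                n_perm = 6000L, cdt_p = 0.001, seed = 1L) {
  ma <- report_a$contrast_maps[[contrast]]
  mb <- report_b$contrast_maps[[contrast]]
  if (is.null(ma) || is.null(mb))
    stop_tdbold("contrast '", contrast, "' missing from a report")
  if (!identical(dim(ma[[1]]), dim(mb[[1]])) ||
      !isTRUE(all.equal(report_a$phantom$affine, report_b$phantom$affine)))
    stop_tdbold("analysis grids do not match between the two runs; ",
                "resimulate both cohorts on a common grid first")
  maps <- c(ma, mb)
  labels <- rep(c("a", "b"), c(length(ma), length(mb)))
  grp <- second_level(maps, "two_sample", group_labels = labels)
  null <- permutation_correct(maps, n_perm = n_perm, cdt_p = cdt_p,
                              analysis_type = "two_sample",
                              group_labels = labels, seed = seed)
  list(group = grp, null = null,
       table = cluster_report(null, report_a$phantom))
}
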