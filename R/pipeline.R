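#' Pipeline configuration
#'
#' Bundles the per-stage settings of the end-to-end pipeline: gradient
#' segmentation parameters, the jitter applied to the second
#' segmentation realization (a proxy for intra-observer re-draws),
#' physics constants, radiobiology parameters and the lesion exclusion
#' thresholds (morphologic volume below 2 cm^3, or no uptake, defined as
#' a mean absorbed dose below 5 Gy in the morphologic mask).
#'
#' @param gradient A [gradient_params()] (first realization; jitter is
#'   forced to 0).
#' @param repeat_jitter_sigma_mm Jitter of the second realization, mm.
#' @param physics A [physics_constants()].
#' @param radiobiology A [radiobiology_params()].
#' @param min_volume_cm3,min_mean_dose_gy Exclusion thresholds.
#' @export
pipeline_config <- function(gradient = gradient_params(),
                            repeat_jitter_sigma_mm = 2,
                            physics = physics_constants(),
                            radiobiology = radiobiology_params(),
                            min_volume_cm3 = 2, min_mean_dose_gy = 5) {
  gradient$jitter_sigma <- 0
  structure(list(gradient = gradient,
                 repeat_jitter_sigma_mm = repeat_jitter_sigma_mm,
                 physics = physics, radiobiology = radiobiology,
                 min_volume_cm3 = min_volume_cm3,
                 min_mean_dose_gy = min_mean_dose_gy),
            class = "pipeline_config")
}

#' Analyze one lesion end to end
#'
#' Computes the absorbed-dose map (local deposition), runs the gradient
#' segmentation twice — the second realization from a jittered
#' initialization, emulating an intra-observer repeat — and reports dose
#' metrics for the morphologic mask (MS) and both PET-based realizations
#' (PS1, PS2), spatial concordance of PS1 vs MS and PS1 vs PS2, and the
#' exclusion status.  Exclusion rules evaluate on the MS volume and MS
#' mean dose only, so they are identical for every segmentation method.
#'
#' @param pet A [voxel_image] in Bq/mL.
#' @param ms The morphologic [voi_mask] on the same grid.
#' @param config A [pipeline_config()].
#' @param seed Integer seed (fixes the jittered realization).
#' @param dose Optional precomputed dose map (to share across lesions of
#'   one case).
#' @param patient_id,lesion_id Identifiers carried into the result.
#' @return A `lesion_result` list.
#' @export
run_lesion <- function(pet, ms, config = pipeline_config(), seed = 1L,
                       dose = NULL, patient_id = "P01", lesion_id = "L1") {
  stopifnot(inherits(pet, "voxel_image"), inherits(ms, "voi_mask"))
  stop_if_grid_mismatch(pet, ms, "PET and MS mask")
  if (is.null(dose)) dose <- activity_to_dose_local(pet, config$physics)
  res <- list(patient_id = patient_id, lesion_id = lesion_id,
              excluded = FALSE, exclusion_reason = NA_character_)
  class(res) <- "lesion_result"
  ms_vol <- volume_cm3(ms)
  if (ms_vol < config$min_volume_cm3) {
    res$excluded <- TRUE
    res$exclusion_reason <- "volume_lt_2cm3"
    res$ms_metrics <- list(volume_cm3 = ms_vol)
    return(res)
  }
  ms_dvh <- compute_dvh(dose, ms)
  res$ms_metrics <- dose_metrics(ms_dvh, config$radiobiology)
  if (res$ms_metrics$mean_Gy < config$min_mean_dose_gy) {
    res$excluded <- TRUE
    res$exclusion_reason <- "no_uptake_lt_5Gy"
    return(res)
  }
  init <- init_from_mask(ms)
  p1 <- config$gradient
  p1$jitter_sigma <- 0
  ps1 <- segment_with_nudge(pet, ms, init, p1)
  p2 <- config$gradient
  p2$jitter_sigma <- config$repeat_jitter_sigma_mm
  ps2 <- segment_with_nudge(pet, ms, init, p2,
                            seed = child_seed(seed, paste0("ps2_", lesion_id)))
  res$ps1_metrics <- dose_metrics(compute_dvh(dose, ps1),
                                  config$radiobiology)
  res$ps2_metrics <- dose_metrics(compute_dvh(dose, ps2),
                                  config$radiobiology)
  res$ps_mean_metrics <- average_metrics(res$ps1_metrics, res$ps2_metrics)
  res$concordance <- concordance(ms, ps1)
  res$ps_repeat_concordance <- concordance(ps1, ps2)
  res$masks <- list(ms = ms, ps1 = ps1, ps2 = ps2)
  res
}

# If the MS-centroid initialization sees no falling edge (seed stranded
# in a non-perfused part of the lesion), emulate the operator nudging
# the starting point onto the uptake: re-seed at the hottest smoothed
# PET voxel inside the MS and retry.
segment_with_nudge <- function(pet, ms, init, params, seed = NULL) {
  tryCatch(gradient_segment(pet, init, params, seed = seed),
    error = function(e) {
      if (!grepl("degenerate", conditionMessage(e))) stop(e)
      sm <- gaussian_blur_vox(pet$values, rep(1, 3))
      sm[!ms$values] <- -Inf
      hot <- arrayInd(which.max(sm), dim(sm))
      init2 <- init_at_voxel(ms, as.integer(hot), margin = init$margin)
      gradient_segment(pet, init2, params, seed = seed)
    })
}

average_metrics <- function(a, b) {
  out <- a
  for (k in names(a)) out[[k]] <- (a[[k]] + b[[k]]) / 2
  out
}

#' @export
print.lesion_result <- function(x, ...) {
  if (x$excluded) {
    cat(sprintf("<lesion_result> %s/%s EXCLUDED (%s)\n",
                x$patient_id, x$lesion_id, x$exclusion_reason))
  } else {
    cat(sprintf("<lesion_result> %s/%s MS %.3g cm^3, PS1 %.3g cm^3, DSC %.3f, MDA %.2f mm\n",
                x$patient_id, x$lesion_id, x$ms_metrics$volume_cm3,
                x$ps1_metrics$volume_cm3, x$concordance$dsc,
                x$concordance$mda_mm))
  }
  invisible(x)
}

metric_names <- c("volume_cm3", "mean_Gy", "d70_Gy", "d90_Gy",
                  "bed_mean_Gy", "bed70_Gy", "bed90_Gy")

#' Run a cohort of cases through the pipeline
#'
#' Analyzes every lesion of every case (one dose map per case), builds
#' the per-lesion table, and summarizes the cohort: per-metric
#' mean/sd/five-number summaries for MS and PS (PS = average of the two
#' realizations), paired PS - MS differences with patient-level
#' bootstrap confidence intervals, and Pearson/concordance correlation
#' per metric.
#'
#' @param cases List of case objects from [make_patient_cohort()] or
#'   [make_phantom_suite()] (the phantom truth masks double as MS).
#' @param config A [pipeline_config()].
#' @param seed Integer master seed (segmentation jitter and bootstrap).
#' @param n_boot Bootstrap replicates for the summary statistics.
#' @return A `cohort_result` with elements `lesions` (data frame),
#'   `results` (list of `lesion_result`) and `summary` (per-metric
#'   statistics); errors if every lesion is excluded.
#' @export
run_cohort <- function(cases, config = pipeline_config(), seed = 1L,
                       n_boot = 2000) {
  stopifnot(length(cases) >= 1)
  results <- list()
  for (case in cases) {
    dose <- activity_to_dose_local(case$pet, config$physics)
    ms_masks <- if (!is.null(case$ms_masks)) case$ms_masks else case$truth_masks
    labels <- if (!is.null(case$lesion_labels)) case$lesion_labels
      else sprintf("%s_L%d", case$id, seq_along(ms_masks))
    for (i in seq_along(ms_masks)) {
      r <- run_lesion(case$pet, ms_masks[[i]], config,
                      seed = child_seed(seed, labels[i]), dose = dose,
                      patient_id = case$patient_id, lesion_id = labels[i])
      r$masks <- NULL                       # keep the cohort object small
      results[[length(results) + 1L]] <- r
    }
  }
  keep <- !vapply(results, `[[`, logical(1), "excluded")
  if (!any(keep))
    stop("empty cohort: all lesions were excluded", call. = FALSE)
  lesions <- do.call(rbind, lapply(results[keep], function(r) {
    row <- data.frame(patient_id = r$patient_id, lesion_id = r$lesion_id,
                      dsc = r$concordance$dsc,
                      mda_mm = r$concordance$mda_mm,
                      repeat_dsc = r$ps_repeat_concordance$dsc,
                      repeat_mda_mm = r$ps_repeat_concordance$mda_mm,
                      stringsAsFactors = FALSE)
    for (m in metric_names) {
      row[[paste0("ms_", m)]] <- r$ms_metrics[[m]]
      row[[paste0("ps_", m)]] <- r$ps_mean_metrics[[m]]
    }
    row
  }))
  summary <- lapply(stats::setNames(metric_names, metric_names), function(m) {
    x <- lesions[[paste0("ms_", m)]]
    y <- lesions[[paste0("ps_", m)]]
    agr <- if (length(unique(lesions$patient_id)) >= 2)
      paired_mean_difference(paired_sample(x, y, lesions$patient_id),
                             n_boot = n_boot,
                             seed = child_seed(seed, paste0("boot_", m)))
    else NULL
    list(ms = c(mean = mean(x), sd = stats::sd(x),
                stats::setNames(stats::fivenum(x),
                                c("min", "q1", "median", "q3", "max"))),
         ps = c(mean = mean(y), sd = stats::sd(y),
                stats::setNames(stats::fivenum(y),
                                c("min", "q1", "median", "q3", "max"))),
         agreement = agr)
  })
  structure(list(lesions = lesions, results = results, summary = summary,
                 n_excluded = sum(!keep), seed = seed),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %d lesions analyzed, %d excluded\n",
              nrow(x$lesions), x$n_excluded))
  for (m in c("mean_Gy", "d70_Gy", "d90_Gy")) {
    a <- x$summary[[m]]$agreement
    if (!is.null(a))
      cat(sprintf("  %-8s PS-MS %+.3g Gy [%.3g, %.3g], r=%.3f, ccc=%.3f\n",
                  m, a$mean_diff, a$ci_low, a$ci_high, a$pearson_r, a$ccc))
  }
  invisible(x)
}

#' Phantom-suite validation report
#'
#' Builds the three-phantom suite, runs the full pipeline on each of the
#' five lesions (8, 16, 29, 60-warm, 60-cold cm^3), and reports per
#' lesion the relative volume error, the relative differences in
#' mean/D70/D90 of PS vs MS (relative to the MS value), DSC and MDA, and
#' the PS1-vs-PS2 repeatability (DSC, MDA and relative AD/BED metric
#' differences).  The report also checks the reference bounds of the
#' simulated validation: volume within 15%, dose metrics within 11%,
#' DSC >= 0.86 and MDA <= 1.5 mm against MS; repeat DSC >= 0.99 and
#' metric differences within 2%.
#'
#' @param seed Integer master seed.
#' @param config A [pipeline_config()].
#' @param noise A [noise_spec()] for the suite.
#' @return A `phantom_report`: `lesions` data frame, `checks` list and
#'   `pass` flag.
#' @export
run_phantom_acceptance <- function(seed = 1L, config = pipeline_config(),
                                   noise = noise_spec()) {
  suite <- make_phantom_suite(seed = seed, noise = noise)
  rows <- list()
  for (case in suite) {
    dose <- activity_to_dose_local(case$pet, config$physics)
    for (i in seq_along(case$truth_masks)) {
      lab <- case$lesion_labels[i]
      r <- run_lesion(case$pet, case$truth_masks[[i]], config,
                      seed = child_seed(seed, lab), dose = dose,
                      patient_id = case$id, lesion_id = lab)
      relerr <- function(a, b) (a - b) / b * 100
      ms <- r$ms_metrics; p1 <- r$ps1_metrics; p2 <- r$ps2_metrics
      rep_rel <- vapply(c("mean_Gy", "d70_Gy", "d90_Gy", "bed_mean_Gy",
                          "bed70_Gy", "bed90_Gy"), function(m)
        abs(p1[[m]] - p2[[m]]) / p1[[m]] * 100, numeric(1))
      rows[[lab]] <- data.frame(
        lesion = lab,
        ms_volume_cm3 = ms$volume_cm3,
        ps1_volume_cm3 = p1$volume_cm3,
        ps2_volume_cm3 = p2$volume_cm3,
        volume_err_pct = relerr(p1$volume_cm3, ms$volume_cm3),
        dmean_pct = relerr(p1$mean_Gy, ms$mean_Gy),
        d70_pct = relerr(p1$d70_Gy, ms$d70_Gy),
        d90_pct = relerr(p1$d90_Gy, ms$d90_Gy),
        dsc = r$concordance$dsc,
        mda_mm = r$concordance$mda_mm,
        repeat_dsc = r$ps_repeat_concordance$dsc,
        repeat_mda_mm = r$ps_repeat_concordance$mda_mm,
        repeat_metric_max_pct = max(rep_rel),
        stringsAsFactors = FALSE)
    }
  }
  lesions <- do.call(rbind, rows)
  rownames(lesions) <- NULL
  checks <- list(
    volume_within_15pct = max(abs(lesions$volume_err_pct)) <= 15,
    dose_metrics_within_11pct =
      max(abs(c(lesions$dmean_pct, lesions$d70_pct, lesions$d90_pct))) <= 11,
    dsc_ge_0.86 = min(lesions$dsc) >= 0.86,
    mda_le_1.5mm = max(lesions$mda_mm) <= 1.5,
    repeat_dsc_ge_0.99 = min(lesions$repeat_dsc) >= 0.99,
    repeat_metrics_within_2pct = max(lesions$repeat_metric_max_pct) <= 2)
  structure(list(lesions = lesions, checks = checks,
                 pass = all(unlist(checks)), seed = seed),
            class = "phantom_report")
}

#' @export
print.phantom_report <- function(x, ...) {
  cat("<phantom_report> seed", x$seed, if (x$pass) "PASS" else "FAIL", "\n")
  print(x$lesions[, c("lesion", "ms_volume_cm3", "ps1_volume_cm3",
                      "volume_err_pct", "dmean_pct", "d70_pct", "d90_pct",
                      "dsc", "mda_mm", "repeat_dsc",
                      "repeat_metric_max_pct")],
        digits = 3, row.names = FALSE)
  for (nm in names(x$checks))
    cat(sprintf("  %-28s %s\n", nm, if (x$checks[[nm]]) "ok" else "FAIL"))
  invisible(x)
}

#' Write a phantom report as JSON
#'
#' @param report A [run_phantom_acceptance()] result.
#' @param path Output JSON path.
#' @export
write_phantom_report <- function(report, path) {
  stopifnot(inherits(report, "phantom_report"))
  jsonlite::write_json(list(seed = report$seed, pass = report$pass,
                            checks = report$checks,
                            lesions = report$lesions),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
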