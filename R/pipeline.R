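#' Filter a cohort by etiology
#'
#' @param cohort A `vmre_cohort` data frame.
#' @param etiology One of `"HBV"`, `"MASLD"`, `"other"`.
#' @return The filtered cohort, order preserved; a warning is issued when
#'   the result is empty (downstream stages should then be skipped).
#' @export
subset_by_etiology <- function(cohort, etiology) {
  etiology <- match.arg(etiology, c("HBV", "MASLD", "other"))
  out <- cohort[cohort$etiology == etiology, , drop = FALSE]
  if (!nrow(out)) warning(sprintf("no patients with etiology %s", etiology))
  attr(out, "provenance") <- attr(cohort, "provenance")
  class(out) <- class(cohort)
  out
}

# Per-patient analysis values: reader-mean VMRE, acquisition-mean USE.
analysis_values <- function(cohort) {
  data.frame(id = cohort$id, stage = cohort$stage, etiology = cohort$etiology,
             vmre = combine_readers(cohort$vmre_r1, cohort$vmre_r2),
             use = (cohort$use_a1 + cohort$use_a2) / 2)
}

# Degenerate cohorts make individual statistics undefined; report the named
# error inside the block instead of aborting the whole run.
safe_block <- function(expr) {
  tryCatch(expr, error = function(e) list(error = conditionMessage(e)))
}

stats_block <- function(av, label, seed) {
  by_stage <- function(col) {
    present <- levels(droplevels(av$stage))
    stats::setNames(lapply(present, function(s) av[[col]][av$stage == s]),
                    present)
  }
  roc_block <- function(col, scheme) {
    safe_block({
      lab <- binarize_stage(av$stage, scheme) == "positive"
      if (length(unique(lab)) < 2)
        stop(sprintf("%s %s: single-class labels, ROC undefined", label, scheme))
      r <- roc_analysis(av[[col]], lab, seed = seed)
      r$curve <- NULL
      unclass(r)
    })
  }
  kw <- safe_block(unclass(kruskal_wallis(by_stage("vmre"))))
  dunn <- safe_block(dunn_posthoc(by_stage("vmre")))
  aov_use <- safe_block(unclass(one_way_anova(by_stage("use"))))
  list(
    n = nrow(av),
    descriptives = list(vmre = descriptive_by_stage(av, "vmre"),
                        use = descriptive_by_stage(av, "use")),
    kruskal_wallis_vmre = kw,
    dunn_vmre = dunn,
    anova_use = aov_use,
    roc = list(vmre_F01_vs_F24 = roc_block("vmre", "F01_vs_F24"),
               vmre_F02_vs_F34 = roc_block("vmre", "F02_vs_F34"),
               use_F01_vs_F24 = roc_block("use", "F01_vs_F24"),
               use_F02_vs_F34 = roc_block("use", "F02_vs_F34"))
  )
}

#' Run the full synthetic-cohort analysis end to end
#'
#' Orchestrates simulate -> map -> ROI -> stage -> statistics: generates the
#' cohort, exercises the imaging path (phantom, sADC/VMRE maps, 3-slice ROI
#' aggregation) on a small subset of stages, computes per-patient analysis
#' values, stages them against the fixed MRE thresholds, and runs the
#' statistical battery on the full cohort and on the HBV subset separately.
#' Statistics blocks that are undefined for a degenerate cohort (e.g. a
#' single represented class) are reported as named errors rather than
#' aborting the run; failures in the simulation/mapping stages abort with
#' the stage named.
#'
#' @param config A [simulation_config()].
#' @param outdir Output directory (created if needed).
#' @param phantom_stages Stages for which the imaging path is exercised
#'   (default `"F2"`; the cohort statistics path does not depend on it).
#' @param write_maps Also write NIfTI phantom/map volumes (default FALSE to
#'   keep runs light).
#' @return A list of class `vmre_run`: `report` (the full analysis report)
#'   and `manifest` (config snapshot, seed, file paths, versions, per-stage
#'   wall-clock). The report is written to `<outdir>/report.json`, the
#'   cohort to `<outdir>/cohort.csv`, the manifest to
#'   `<outdir>/manifest.json`.
#' @export
run_all <- function(config = simulation_config(), outdir = tempfile("vmre_run_"),
                    phantom_stages = "F2", write_maps = FALSE) {
  stopifnot(inherits(config, "vmre_sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed,
                   config = config_snapshot(config),
                   version = as.character(utils::packageVersion("vmre")),
                   files = list(), timing_s = list())
  tic <- function() proc.time()[["elapsed"]]
  run_stage <- function(name, expr) {
    t0 <- tic()
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
    manifest$timing_s[[name]] <<- round(tic() - t0, 3)
    message(sprintf("[%s] done in %.2fs", name, tic() - t0))
    res
  }

  cohort <- run_stage("simulate", generate_cohort(config))
  cohort_path <- file.path(outdir, "cohort.csv")
  write_cohort_csv(cohort, cohort_path)
  manifest$files$cohort <- cohort_path

  imaging <- run_stage("map_roi", {
    lapply(stats::setNames(phantom_stages, phantom_stages), function(st) {
      ph <- generate_phantom(config, st,
                             out_prefix = if (write_maps)
                               file.path(outdir, paste0("phantom_", st)) else NULL)
      vmre_map <- sadc_to_vmre(compute_sadc_map(ph$dwi))
      mid <- dim(ph$label)[3] %/% 2
      rois <- roi_set(lapply((mid - 1):(mid + 1), function(z)
        list(slice = z, mask = ph$label[, , z] == 1)), modality = "VMRE")
      ms <- summarize_map_over_rois(vmre_map, rois, stat = "mean")
      list(stage = st, summary_kpa = ms$summary,
           truth_mean_kpa = mean(ph$stiffness[ph$label == 1]),
           files = ph$files)
    })
  })

  av <- analysis_values(cohort)
  staging <- run_stage("stage", {
    pred <- classify_stage(av$vmre)
    conc <- concordance_summary(pred, av$stage)
    hbv <- av$etiology == "HBV"
    conc_hbv <- if (any(hbv))
      concordance_summary(pred[hbv], av$stage[hbv]) else NULL
    list(all = conc, hbv = conc_hbv)
  })

  stats_all <- run_stage("stats_all", stats_block(av, "all",
                                                  substream(config$seed, "roc_all")))
  hbv_cohort <- subset_by_etiology(cohort, "HBV")
  stats_hbv <- if (nrow(hbv_cohort))
    run_stage("stats_hbv", stats_block(analysis_values(hbv_cohort), "HBV",
                                       substream(config$seed, "roc_hbv")))
  else list(skipped = "empty HBV subset")

  agreement <- run_stage("agreement", list(
    vmre_readers = c(unclass(icc_agreement(cbind(cohort$vmre_r1, cohort$vmre_r2))),
                     unclass(bland_altman(cohort$vmre_r1, cohort$vmre_r2))[
                       c("mean_diff", "sd_diff", "loa", "loa_1sd")]),
    use_acquisitions = c(unclass(icc_agreement(cbind(cohort$use_a1, cohort$use_a2))),
                         unclass(bland_altman(cohort$use_a1, cohort$use_a2))[
                           c("mean_diff", "sd_diff", "loa", "loa_1sd")])
  ))

  report <- list(
    schema = "vmre-report/1",
    seed = config$seed,
    cohort = list(n = nrow(cohort),
                  n_hbv = sum(cohort$etiology == "HBV"),
                  stage_counts = as.list(table(cohort$stage))),
    imaging_check = lapply(imaging, function(x) x[c("stage", "summary_kpa",
                                                    "truth_mean_kpa")]),
    staging = list(
      all = unclass_staging(staging$all),
      hbv = if (!is.null(staging$hbv)) unclass_staging(staging$hbv)),
    statistics = list(all = stats_all, hbv = stats_hbv),
    agreement = agreement
  )
  report_path <- file.path(outdir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", dataframe = "rows")
  manifest$files$report <- report_path
  manifest$files$phantoms <- unlist(lapply(imaging, `[[`, "files"))
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  structure(list(report = report, manifest = manifest, outdir = outdir),
            class = "vmre_run")
}

config_snapshot <- function(config) {
  s <- unclass(config)
  s$stage_counts <- as.list(s$stage_counts)
  s$snr <- if (is.finite(s$snr)) s$snr else "Inf"
  s
}

unclass_staging <- function(x) {
  x <- unclass(x)
  x$predicted <- as.character(x$predicted)
  x
}
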