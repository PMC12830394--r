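#' Fixed MRE stage-threshold table
#'
#' Per-stage liver stiffness (mean, SD) on the conventional MRE scale, used
#' to categorize virtual-elastography values into METAVIR stages. Defaults
#' are the published standard thresholds: F0 2.13±0.27, F1 2.49±0.28,
#' F2 2.83±0.32, F3 3.6±0.81, F4 5.2±1.02 kPa. Two boundary rules are
#' available: `"midpoint"` places stage boundaries halfway between
#' consecutive means (default; with the default means the boundaries are
#' 2.31, 2.66, 3.215 and 4.4 kPa); `"nearest_mean"` assigns the stage whose
#' mean is closest. Boundary ties go to the lower (less severe) stage.
#'
#' @param means Named or ordered numeric vector of 5 per-stage means (kPa),
#'   strictly increasing F0 to F4.
#' @param sds Per-stage SDs (kPa), carried for reference (unused by the
#'   hard-boundary rules).
#' @param boundary_rule `"midpoint"` or `"nearest_mean"`.
#' @return An object of class `stage_threshold_table`.
#' @export
stage_threshold_table <- function(means = MRE_STAGE_STIFFNESS$mean_kpa,
                                  sds = MRE_STAGE_STIFFNESS$sd_kpa,
                                  boundary_rule = c("midpoint", "nearest_mean")) {
  boundary_rule <- match.arg(boundary_rule)
  if (length(means) != 5L || length(sds) != 5L)
    stop("need one (mean, sd) pair per METAVIR stage", call. = FALSE)
  if (any(diff(means) <= 0))
    stop("table error: stage means must be strictly increasing F0 -> F4",
         call. = FALSE)
  if (any(sds < 0)) stop("SDs must be non-negative", call. = FALSE)
  structure(list(stage = METAVIR_STAGES, means = as.numeric(means),
                 sds = as.numeric(sds), boundary_rule = boundary_rule,
                 boundaries = (means[-5] + means[-1]) / 2),
            class = "stage_threshold_table")
}

#' Classify a stiffness value into a METAVIR stage
#'
#' Under the midpoint rule a value below the first boundary is F0 and above
#' the last is F4; a value exactly on a boundary takes the lower stage.
#' Under the nearest-mean rule the closest stage mean wins, ties to the
#' lower stage. Both rules are monotone non-decreasing in the value and map
#' each stage mean to its own stage.
#'
#' @param value_kpa Positive stiffness value(s) in kPa; vectorized.
#' @param table A [stage_threshold_table()].
#' @return Ordered factor with levels F0..F4.
#' @export
classify_stage <- function(value_kpa, table = stage_threshold_table()) {
  stopifnot(inherits(table, "stage_threshold_table"))
  if (any(!is.finite(value_kpa)) || any(value_kpa <= 0))
    stop("stiffness values must be positive", call. = FALSE)
  idx <- if (table$boundary_rule == "midpoint") {
    # value == boundary counts as the lower stage (strict >)
    1L + rowSums(outer(value_kpa, table$boundaries, ">"))
  } else {
    apply(abs(outer(value_kpa, table$means, "-")), 1L, which.min)
  }
  factor(METAVIR_STAGES[idx], levels = METAVIR_STAGES, ordered = TRUE)
}

#' Binarize a METAVIR stage
#'
#' Two clinical groupings: significant fibrosis (`"F01_vs_F24"`, positive =
#' F2 or higher) and advanced fibrosis (`"F02_vs_F34"`, positive = F3 or
#' higher).
#'
#' @param stage Factor/character of stages F0..F4; vectorized.
#' @param scheme `"F01_vs_F24"` or `"F02_vs_F34"`.
#' @return Factor with levels `negative`, `positive`.
#' @export
binarize_stage <- function(stage, scheme = c("F01_vs_F24", "F02_vs_F34")) {
  scheme <- match.arg(scheme)
  s <- as.character(stage)
  if (!all(s %in% METAVIR_STAGES)) stop("unknown stage value", call. = FALSE)
  cut_at <- if (scheme == "F01_vs_F24") "F2" else "F3"
  pos <- match(s, METAVIR_STAGES) >= match(cut_at, METAVIR_STAGES)
  factor(ifelse(pos, "positive", "negative"),
         levels = c("negative", "positive"))
}

#' Concordance between predicted and reference stages
#'
#' Exact-match and within-one-stage counts, plus binary concordance under
#' both clinical groupings. Percentages are rounded to integers for
#' reporting, mirroring the clinical summary format.
#'
#' @param predicted,reference Equal-length stage vectors (F0..F4).
#' @return A list of class `staging_result`: `n`, `predicted`, `exact_count`,
#'   `exact_pct`, `within_one_count`, `within_one_pct`, and a `binary` list
#'   with per-scheme `count`/`pct`.
#' @export
concordance_summary <- function(predicted, reference) {
  if (length(predicted) != length(reference) || !length(predicted))
    stop("predicted and reference must be non-empty and of equal length",
         call. = FALSE)
  pi <- match(as.character(predicted), METAVIR_STAGES)
  ri <- match(as.character(reference), METAVIR_STAGES)
  if (anyNA(pi) || anyNA(ri)) stop("unknown stage value", call. = FALSE)
  n <- length(pi)
  exact <- sum(pi == ri)
  within1 <- sum(abs(pi - ri) <= 1)
  binary <- lapply(c(F01_vs_F24 = "F01_vs_F24", F02_vs_F34 = "F02_vs_F34"),
                   function(sch) {
    cnt <- sum(binarize_stage(predicted, sch) == binarize_stage(reference, sch))
    list(count = cnt, pct = round(100 * cnt / n))
  })
  structure(list(n = n,
                 predicted = factor(METAVIR_STAGES[pi],
                                    levels = METAVIR_STAGES, ordered = TRUE),
                 exact_count = exact, exact_pct = round(100 * exact / n),
                 within_one_count = within1,
                 within_one_pct = round(100 * within1 / n),
                 binary = binary),
            class = "staging_result")
}

#' Write / read a stage-threshold table as CSV
#'
#' Columns `stage,mean_kpa,sd_kpa`.
#'
#' @param table A [stage_threshold_table()].
#' @param path CSV path.
#' @param boundary_rule Rule applied to a table read back from CSV.
#' @return `path` (write, invisibly) or a `stage_threshold_table` (read).
#' @export
write_threshold_csv <- function(table, path) {
  utils::write.csv(data.frame(stage = table$stage, mean_kpa = table$means,
                              sd_kpa = table$sds),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_threshold_csv
#' @export
read_threshold_csv <- function(path, boundary_rule = "midpoint") {
  df <- utils::read.csv(path)
  df <- df[match(METAVIR_STAGES, df$stage), ]
  stage_threshold_table(df$mean_kpa, df$sd_kpa, boundary_rule)
}
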