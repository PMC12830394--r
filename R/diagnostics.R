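#' Empirical ROC analysis with Youden-index cutoff
#'
#' Builds the empirical ROC over all distinct observed thresholds with the
#' convention "value >= cutoff is test-positive" (higher stiffness indicates
#' more fibrosis). AUC is the trapezoidal area under the curve, which equals
#' the Mann-Whitney pairwise-concordance statistic with ties counted 1/2.
#' The operating cutoff maximizes the Youden index J = sensitivity +
#' specificity - 1 over the observed values; ties are broken by higher
#' specificity, then by the lower cutoff. The AUC confidence interval is a
#' seeded stratified bootstrap (percentile method).
#'
#' @param values Numeric test values (kPa), one per subject.
#' @param labels Binary reference labels (logical, 0/1, or a factor whose
#'   second level is positive).
#' @param n_boot Bootstrap resamples for the AUC CI (default 2000; 0
#'   disables).
#' @param seed Seed for the bootstrap.
#' @param conf Confidence level (default 0.95).
#' @return A list of class `roc_result`: `auc`, `ci_auc`, `cutoff`,
#'   `youden_j`, `sensitivity`, `specificity`, `ppv`, `npv`, `accuracy`,
#'   `curve` (data frame `threshold`, `fpr`, `tpr`), `n_pos`, `n_neg`.
#' @export
roc_analysis <- function(values, labels, n_boot = 2000, seed = NULL,
                         conf = 0.95) {
  lab <- as_binary_labels(labels)
  if (length(values) != length(lab))
    stop("values and labels must have equal length", call. = FALSE)
  if (anyNA(values) || anyNA(lab)) stop("missing values not allowed", call. = FALSE)
  pos <- values[lab]; neg <- values[!lab]
  if (!length(pos) || !length(neg))
    stop("both classes must be non-empty", call. = FALSE)

  thr <- sort(unique(values))
  tp <- vapply(thr, function(t) sum(pos >= t), numeric(1))
  fp <- vapply(thr, function(t) sum(neg >= t), numeric(1))
  tpr <- tp / length(pos)
  fpr <- fp / length(neg)
  curve <- data.frame(threshold = c(Inf, rev(thr)),
                      fpr = c(0, rev(fpr)), tpr = c(0, rev(tpr)))
  curve <- rbind(curve, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  auc <- trapezoid_auc(curve$fpr, curve$tpr)

  # argmax of J = tp/n_pos - fp/n_neg over observed thresholds, maximized on
  # the integer score tp*n_neg - fp*n_pos so that exact J ties are not broken
  # by floating-point rounding; ties -> highest specificity (lowest fp),
  # then lowest cutoff
  score <- tp * length(neg) - fp * length(pos)
  best <- which(score == max(score))
  best <- best[order(fp[best], thr[best])][1]
  cutoff <- thr[best]
  sens <- tpr[best]; spec <- 1 - fpr[best]
  tp <- sum(pos >= cutoff); fp <- sum(neg >= cutoff)
  tn <- sum(neg < cutoff); fn <- sum(pos < cutoff)
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_

  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    ci <- with_seed(seed, {
      reps <- vapply(seq_len(n_boot), function(i) {
        p <- sample(pos, length(pos), replace = TRUE)
        q <- sample(neg, length(neg), replace = TRUE)
        concordance_auc(p, q)
      }, numeric(1))
      unname(stats::quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                             type = 7))
    })
  }
  structure(list(auc = auc, ci_auc = ci, cutoff = cutoff,
                 youden_j = sens + spec - 1,
                 sensitivity = sens, specificity = spec,
                 ppv = ppv, npv = npv,
                 accuracy = (tp + tn) / length(values),
                 curve = curve, n_pos = length(pos), n_neg = length(neg)),
            class = "roc_result")
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) {
    if (nlevels(labels) != 2) stop("labels must be binary", call. = FALSE)
    return(labels == levels(labels)[2])
  }
  u <- sort(unique(labels))
  if (!all(u %in% c(0, 1))) stop("labels must be binary", call. = FALSE)
  labels == 1
}

trapezoid_auc <- function(fpr, tpr) {
  o <- order(fpr, tpr)
  sum(diff(fpr[o]) * (tpr[o][-1] + tpr[o][-length(tpr)]) / 2)
}

# Mann-Whitney pairwise concordance (ties counted 1/2); used by the
# bootstrap, and as the quantity the trapezoidal AUC provably equals.
concordance_auc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  np <- length(pos); nn <- length(neg)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Intraclass correlation: two-way random effects, absolute agreement,
#' single measure
#'
#' ICC(2,1) from the two-way ANOVA mean squares of a subjects-by-raters
#' matrix, with the standard F-based 95% confidence interval. This is the
#' agreement flavor appropriate when the same raters (or repeated
#' acquisitions) measure every subject and systematic rater offsets should
#' count against agreement.
#'
#' @param mat Numeric matrix, subjects in rows (>= 3), raters/acquisitions
#'   in columns (>= 2), no missing cells.
#' @param conf Confidence level (default 0.95).
#' @return A list of class `agreement_result`: `icc`, `icc_ci`, `model`,
#'   mean squares `msr`, `msc`, `mse`.
#' @export
icc_agreement <- function(mat, conf = 0.95) {
  mat <- as.matrix(mat)
  n <- nrow(mat); k <- ncol(mat)
  if (k < 2 || n < 3) stop("need >= 3 subjects and >= 2 raters", call. = FALSE)
  if (anyNA(mat)) stop("no missing cells allowed", call. = FALSE)
  rm_ <- rowMeans(mat); cm <- colMeans(mat); gm <- mean(mat)
  msr <- k * sum((rm_ - gm)^2) / (n - 1)
  msc <- n * sum((cm - gm)^2) / (k - 1)
  sse <- sum((sweep(sweep(mat, 1, rm_), 2, cm) + gm)^2)
  mse <- sse / ((n - 1) * (k - 1))
  total_ss <- sum((mat - gm)^2)
  if (total_ss == 0) {
    warning("zero total variance: ICC undefined")
    return(structure(list(icc = NA_real_, icc_ci = c(NA_real_, NA_real_),
                          model = "ICC(2,1)", msr = msr, msc = msc, mse = mse),
                     class = "agreement_result"))
  }
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  if (mse == 0 && msc == 0) {
    # identical columns with subject variation: perfect agreement
    warning("residual and rater variance are zero: ICC is exactly 1")
    icc <- 1
  }
  alpha <- 1 - conf
  ci <- c(NA_real_, NA_real_)
  if (mse > 0) {
    a <- k * icc / (n * (1 - icc)); b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- stats::qf(1 - alpha / 2, n - 1, v)
    fu <- stats::qf(1 - alpha / 2, v, n - 1)
    lb <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    ub <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
    ci <- c(lb, ub)
  } else if (icc == 1) ci <- c(1, 1)
  structure(list(icc = icc, icc_ci = ci, model = "ICC(2,1)",
                 msr = msr, msc = msc, mse = mse),
            class = "agreement_result")
}

#' Bland-Altman agreement between paired measurements
#'
#' Differences d = m1 - m2: mean difference (bias), sample SD, conventional
#' 95% limits of agreement (mean ± 1.96 SD) and the ± 1 SD band also used in
#' agreement plots.
#'
#' @param m1,m2 Equal-length numeric vectors, >= 2 pairs.
#' @return A list of class `agreement_result`: `mean_diff`, `sd_diff`,
#'   `loa` (mean ± 1.96 SD), `loa_1sd` (mean ± 1 SD), `means`, `diffs`.
#' @export
bland_altman <- function(m1, m2) {
  if (length(m1) != length(m2) || length(m1) < 2)
    stop("need >= 2 complete pairs", call. = FALSE)
  d <- m1 - m2
  md <- mean(d); sdd <- stats::sd(d)
  structure(list(mean_diff = md, sd_diff = sdd,
                 loa = c(md - 1.96 * sdd, md + 1.96 * sdd),
                 loa_1sd = c(md - sdd, md + sdd),
                 means = (m1 + m2) / 2, diffs = d),
            class = "agreement_result")
}

check_groups <- function(groups, min_size = 1L) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need >= 2 groups", call. = FALSE)
  if (any(lengths(groups) < min_size))
    stop(sprintf("every group needs >= %d values", min_size), call. = FALSE)
  invisible(groups)
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H with the chi-square approximation (df = k - 1), as used
#' for non-parametric stage comparisons. The degenerate all-values-tied case
#' returns H = 0, p = 1 with a warning.
#'
#' @param groups List of >= 2 non-empty numeric vectors.
#' @return A list of class `group_comparison`: `statistic` (H), `df`,
#'   `p_value`, `method`.
#' @export
kruskal_wallis <- function(groups) {
  check_groups(groups, 1L)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1L) {
    warning("all values tied: H = 0, p = 1")
    return(structure(list(statistic = 0, df = length(groups) - 1L,
                          p_value = 1, method = "Kruskal-Wallis"),
                     class = "group_comparison"))
  }
  kt <- stats::kruskal.test(x, g)
  structure(list(statistic = unname(kt$statistic), df = unname(kt$parameter),
                 p_value = kt$p.value, method = "Kruskal-Wallis"),
            class = "group_comparison")
}

#' Dunn post hoc pairwise comparisons on pooled ranks
#'
#' For each pair of groups, z = (Rbar_i - Rbar_j) / SE with the pooled-rank
#' SE including the tie correction; two-sided normal p-values; Bonferroni
#' adjustment multiplies by the number of pairs m = k(k-1)/2 and caps at 1
#' (m = 10 for five stages).
#'
#' @param groups Named list of >= 2 non-empty numeric vectors.
#' @param adjust Currently `"bonferroni"` (default) or `"none"`.
#' @return Data frame `group1`, `group2`, `z`, `p_raw`, `p_adj`.
#' @export
dunn_posthoc <- function(groups, adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  check_groups(groups, 1L)
  k <- length(groups)
  nm <- names(groups) %||% as.character(seq_len(k))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_len(k), lengths(groups))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ns <- lengths(groups)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  sig2 <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  out <- data.frame(group1 = nm[pairs[1, ]], group2 = nm[pairs[2, ]],
                    z = NA_real_, p_raw = NA_real_, p_adj = NA_real_,
                    stringsAsFactors = FALSE)
  for (p in seq_len(m)) {
    i <- pairs[1, p]; j <- pairs[2, p]
    se <- sqrt(sig2 * (1 / ns[i] + 1 / ns[j]))
    z <- if (se > 0) (rbar[i] - rbar[j]) / se else 0
    praw <- 2 * stats::pnorm(-abs(z))
    out$z[p] <- z
    out$p_raw[p] <- praw
    out$p_adj[p] <- if (adjust == "bonferroni") min(1, praw * m) else praw
  }
  out
}

#' One-way analysis of variance across groups
#'
#' Classical equal-variance F test (between/within mean squares), used for
#' parametric stage comparisons.
#'
#' @param groups List of >= 2 numeric vectors, each with >= 2 values.
#' @return A list of class `group_comparison`: `statistic` (F), `df`
#'   (numerator, denominator), `p_value`, `method`.
#' @export
one_way_anova <- function(groups) {
  check_groups(groups, 2L)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  within_ss <- sum(unlist(lapply(groups, function(v) (v - mean(v))^2)))
  if (within_ss == 0) {
    warning("zero within-group variance everywhere: F undefined")
    return(structure(list(statistic = NA_real_,
                          df = c(length(groups) - 1L,
                                 length(x) - length(groups)),
                          p_value = NA_real_, method = "one-way ANOVA"),
                     class = "group_comparison"))
  }
  ot <- stats::oneway.test(x ~ g, var.equal = TRUE)
  structure(list(statistic = unname(ot$statistic),
                 df = unname(ot$parameter), p_value = ot$p.value,
                 method = "one-way ANOVA"),
            class = "group_comparison")
}

#' Normality screening by the Lilliefors-corrected Kolmogorov-Smirnov test
#'
#' One-sample KS distance to a Normal with the sample's own mean and SD;
#' because the parameters are estimated, the null distribution of D is
#' simulated (seeded Monte-Carlo), not taken from the standard KS tables.
#' p > 0.05 is read as compatible with normality.
#'
#' @param values Numeric sample, >= 5 values.
#' @param n_sim Monte-Carlo replicates (default 2000).
#' @param seed Seed for the simulation.
#' @return A list: `statistic` (D), `p_value`, `n_sim`.
#' @export
ks_normality <- function(values, n_sim = 2000, seed = NULL) {
  if (length(values) < 5) stop("need >= 5 values", call. = FALSE)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    warning("zero variance: normality test degenerate")
    return(list(statistic = NA_real_, p_value = NA_real_, n_sim = 0L))
  }
  n <- length(values)
  d_obs <- lilliefors_d(values)
  d_sim <- with_seed(seed, vapply(seq_len(n_sim), function(i)
    lilliefors_d(stats::rnorm(n)), numeric(1)))
  list(statistic = d_obs,
       p_value = (sum(d_sim >= d_obs) + 1) / (n_sim + 1),
       n_sim = n_sim)
}

lilliefors_d <- function(x) {
  z <- sort((x - mean(x)) / stats::sd(x))
  n <- length(z)
  p <- stats::pnorm(z)
  max(pmax(seq_len(n) / n - p, p - (seq_len(n) - 1) / n))
}

#' Per-stage descriptive statistics
#'
#' Mirrors the clinical descriptive format: per stage n, mean ± SD
#' (min-max) and median (Q1-Q3), quartiles by linear interpolation.
#'
#' @param cohort A `vmre_cohort` (or any data frame with a `stage` column).
#' @param variable Column name to summarize.
#' @return Data frame with one row per stage present.
#' @export
descriptive_by_stage <- function(cohort, variable) {
  stopifnot(variable %in% names(cohort))
  stages <- levels(factor(cohort$stage))
  rows <- lapply(stages, function(s) {
    v <- cohort[[variable]][cohort$stage == s]
    if (!length(v)) return(NULL)
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(stage = s, n = length(v), mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else 0,
               min = min(v), max = max(v),
               median = q[2], q1 = q[1], q3 = q[3])
  })
  do.call(rbind, rows)
}
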