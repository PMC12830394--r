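# Independent oracles used across tests. These deliberately avoid the code
# paths they check.

# Scalar-loop sADC: per-voxel log-ratio without vectorized array code.
oracle_sadc_loop <- function(s_lo, s_hi, b_lo = 200, b_hi = 1500) {
  out <- array(NA_real_, dim(s_lo))
  for (i in seq_len(dim(s_lo)[1]))
    for (j in seq_len(dim(s_lo)[2]))
      for (k in seq_len(dim(s_lo)[3])) {
        a <- s_lo[i, j, k]; b <- s_hi[i, j, k]
        if (a > 0 && b > 0) out[i, j, k] <- log(a / b) / (b_hi - b_lo) * 1e3
      }
  out
}

# Pairwise-concordance AUC by explicit enumeration over all (pos, neg) pairs.
oracle_auc_pairs <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Exhaustive Youden scan over observed thresholds with the package's
# tie-break convention re-derived independently.
oracle_youden_scan <- function(values, labels) {
  pos <- values[labels]; neg <- values[!labels]
  thr <- sort(unique(values))
  best <- NULL
  for (t in thr) {
    sens <- mean(pos >= t); spec <- mean(neg < t)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-15 ||
        (abs(j - best$j) <= 1e-15 &&
         (spec > best$spec + 1e-15 ||
          (abs(spec - best$spec) <= 1e-15 && t < best$cutoff))))
      best <- list(cutoff = t, j = j, sens = sens, spec = spec)
  }
  best
}

# Monte-Carlo permutation p-value for the Kruskal-Wallis H (tie-corrected),
# computed directly from ranks without kruskal.test.
oracle_kw_perm_p <- function(groups, n_perm = 1e5, seed = 1) {
  x <- unlist(groups, use.names = FALSE)
  ns <- lengths(groups)
  N <- length(x)
  r <- rank(x)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  h_of <- function(rr) {
    idx <- split(seq_len(N), rep(seq_along(ns), ns))
    rs <- vapply(idx, function(ii) sum(rr[ii]), numeric(1))
    (12 / (N * (N + 1)) * sum(rs^2 / ns) - 3 * (N + 1)) / corr
  }
  h_obs <- h_of(r)
  set.seed(seed)
  h_perm <- replicate(n_perm, h_of(sample(r)))
  list(h = h_obs, p = (sum(h_perm >= h_obs - 1e-12) + 1) / (n_perm + 1))
}

make_constant_map <- function(value, dims = c(4, 4, 4), unit = "kPa") {
  vmre:::new_parametric_map(array(value, dims), unit,
                            array(TRUE, dims), diag(4), c(1, 1, 1))
}
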