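# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: closed forms and exhaustive enumeration only.

# Welch two-sample t-test from the closed-form statistic and
# Welch-Satterthwaite degrees of freedom.
oracle_welch_p <- function(x, y) {
  v1 <- stats::var(x) / length(x)
  v2 <- stats::var(y) / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  2 * stats::pt(-abs(tstat), df)
}

# Exhaustive two-sided label-permutation p-value for a mean difference.
oracle_permutation_p <- function(x, y) {
  pool <- c(x, y)
  idx <- utils::combn(length(pool), length(x))
  obs <- abs(mean(x) - mean(y))
  stat <- apply(idx, 2, function(i)
    abs(mean(pool[i]) - mean(pool[-i])))
  mean(stat >= obs - 1e-12)
}

# Median-of-ratios scale factors (geometric-mean row reference),
# recomputed cell by cell.
oracle_scale_factors <- function(raw, bg_members) {
  sapply(colnames(raw), function(s) {
    ratios <- c()
    for (p in bg_members) {
      row <- raw[p, ]
      ref <- prod(row[!is.na(row)])^(1 / sum(!is.na(row)))
      if (is.na(raw[p, s])) next
      ratios <- c(ratios, raw[p, s] / ref)
    }
    stats::median(ratios)
  })
}

# Pearson r as the covariance ratio, written out longhand.
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Per-sample SINQ recomputation, one line per protein.
oracle_sinq <- function(intensity_vec, lengths_vec) {
  (intensity_vec / sum(intensity_vec)) / lengths_vec
}
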