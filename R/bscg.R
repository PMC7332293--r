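#' Define the background proteome
#'
#' The set of proteins detected in at least a given fraction of all
#' samples, minus known contaminants. These commonly co-purifying
#' proteins anchor the per-sample normalization that makes fold changes
#' comparable across baits.
#'
#' @param qm a [quant_matrix()].
#' @param contaminants character vector of contaminant accessions.
#' @param threshold required detection fraction in (0, 1]; default 0.9 —
#'   "commonly detected" without demanding presence in literally every
#'   run.
#' @return An object of class `BackgroundProteome` with elements
#'   `members` and `threshold`.
#' @export
define_background <- function(qm, contaminants = character(0),
                              threshold = 0.9) {
  stopifnot(threshold > 0, threshold <= 1)
  if (length(qm_baits(qm)) < 2)
    stop("background definition needs >= 2 baits")
  frac <- rowMeans(!is.na(qm$intensity))
  members <- setdiff(qm_proteins(qm)[frac >= threshold], contaminants)
  if (length(members) < 10)
    stop("degenerate background: only ", length(members),
         " proteins detected in >= ", threshold,
         " of samples; lower the threshold")
  structure(list(members = members, threshold = threshold),
            class = "BackgroundProteome")
}

#' Normalize samples to the background proteome
#'
#' Median-of-ratios scaling: each background protein gets a row
#' reference — the geometric mean of its intensity over the samples
#' where it is detected — and each sample's scale factor is the median,
#' over background members detected in it, of intensity / row
#' reference. The geometric-mean reference makes the downstream fold
#' changes and test statistics invariant to rescaling any one sample
#' (the rescaling moves every row reference by a common factor, which
#' cancels); a median reference would not have that property. All cells
#' are divided by the sample's scale factor; missing stays missing.
#' Median ties resolve to the midpoint of the two central order
#' statistics (the default of [stats::median()]).
#'
#' @param qm a [quant_matrix()].
#' @param bg a [define_background()] result.
#' @return An object of class `NormalizedMatrix`: the scaled intensity
#'   grid, per-sample `scale_factors`, and the sample sheet,
#'   unique-peptide and spectral-count grids carried through.
#' @export
normalize_to_background <- function(qm, bg) {
  if (!all(bg$members %in% qm_proteins(qm)))
    stop("background members missing from the quant matrix")
  raw <- qm$intensity
  bgm <- raw[bg$members, , drop = FALSE]
  rowref <- exp(rowMeans(log(bgm), na.rm = TRUE))
  ratios <- bgm / rowref
  nobs <- colSums(!is.na(ratios))
  if (any(nobs < 3))
    stop("sample(s) with < 3 background observations: ",
         paste(colnames(raw)[nobs < 3], collapse = ", "))
  sf <- apply(ratios, 2, stats::median, na.rm = TRUE)
  structure(
    list(intensity = sweep(raw, 2, sf, "/"),
         scale_factors = sf,
         samples = qm$samples,
         unique_peptides = qm$unique_peptides,
         spectral_count = qm$spectral_count,
         background = bg$members),
    class = "NormalizedMatrix")
}

# Per-cell imputation values for all missing cells, drawn once so that
# every bait sees the same value for a given (protein, sample) cell.
# Mean: the sample's 1st percentile of observed log2 intensities (the
# detection-limit region); sd: the median across proteins of the
# within-protein sd of log2 intensities.
.imputation_matrix <- function(ln, seed) {
  mu <- apply(ln, 2, function(v) stats::quantile(v, 0.01, na.rm = TRUE,
                                                 names = FALSE))
  prot_sd <- apply(ln, 1, stats::sd, na.rm = TRUE)
  sd_imp <- stats::median(prot_sd[!is.na(prot_sd) & prot_sd > 0])
  if (!is.finite(sd_imp) || sd_imp <= 0) sd_imp <- 0.3
  imp <- matrix(NA_real_, nrow(ln), ncol(ln), dimnames = dimnames(ln))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  for (j in seq_len(ncol(ln))) {
    miss <- which(is.na(ln[, j]))
    if (length(miss))
      imp[miss, j] <- stats::rnorm(length(miss), mu[j], sd_imp)
  }
  imp
}

.welch_p <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) return(NA_real_)
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  tryCatch(stats::t.test(x, y)$p.value, error = function(e) NA_real_)
}

#' Per-bait enrichment statistics against the bait-specific control group
#'
#' For each protein detected in at least one of the bait's replicates,
#' tests its log2 intensity in the bait's samples against the pooled
#' samples of all other baits. Intensities get a pseudocount (default 1
#' intensity unit) before log2. Missing control cells are imputed from a
#' low-abundance distribution (seeded, one draw per cell shared across
#' baits) provided the protein is observed in at least one control
#' sample; missing bait cells are dropped — detection in the bait with
#' absence elsewhere is signal, not noise. Proteins with zero observed
#' control samples get `p_value = NA` and `n_ctrl_obs = 0`: they are the
#' candidates for the SINQ exclusivity rescue.
#'
#' The imputation is adaptive: a protein observed in at least half of
#' the control samples has its few missing control cells dropped
#' (sporadic missingness there is ignorable, and imputing detection-limit
#' values into an otherwise well-observed group wrecks its variance
#' estimate); a protein observed in fewer than half of the controls has
#' its missing cells imputed from the low-abundance distribution, since
#' widespread absence from the control group is itself evidence of low
#' abundance there.
#'
#' Two test strategies are available. `"moderated"` (default) is a
#' pooled-variance t-test with empirical-Bayes variance shrinkage across
#' proteins (via [limma::squeezeVar()]), which stays calibrated with only
#' two technical duplicates per bait. `"welch"` is the plain Welch
#' two-sample t-test.
#'
#' @param nm a [normalize_to_background()] result.
#' @param bait bait id to score.
#' @param test `"moderated"` or `"welch"`.
#' @param eps pseudocount added to intensities before log2.
#' @param seed integer seed for the imputation draws.
#' @param imputed optional precomputed imputation matrix (internal; lets
#'   [score_all_baits()] share draws across baits).
#' @return data frame with columns `bait_id`, `protein_acc`, `log2fc`,
#'   `p_value`, `q_value` (Benjamini-Hochberg within bait, reported but
#'   never filtered on), `n_bait_obs`, `n_ctrl_obs`.
#' @export
bscg_statistics <- function(nm, bait, test = c("moderated", "welch"),
                            eps = 1, seed = 1L, imputed = NULL) {
  test <- match.arg(test)
  smp <- nm$samples
  if (!bait %in% smp$bait_id) stop("unknown bait: ", bait)
  bidx <- which(smp$bait_id == bait)
  cidx <- which(smp$bait_id != bait)
  if (length(bidx) < 2)
    stop("bait ", bait, " has only ", length(bidx),
         " replicate sample(s); >= 2 needed for a variance estimate")
  if (length(unique(smp$bait_id[cidx])) < 2)
    stop("control group needs samples from >= 2 other baits")

  ln <- log2(nm$intensity + eps)
  if (is.null(imputed)) imputed <- .imputation_matrix(ln, seed)

  bmat <- ln[, bidx, drop = FALSE]
  cobs <- ln[, cidx, drop = FALSE]
  cimp <- imputed[, cidx, drop = FALSE]
  n_bait <- rowSums(!is.na(bmat))
  n_ctrl <- rowSums(!is.na(cobs))
  keep <- which(n_bait >= 1)

  prot <- qm_proteins_nm(nm)[keep]
  nb <- n_bait[keep]; nc <- n_ctrl[keep]
  nctot <- length(cidx)
  d <- s2 <- df <- ny <- rep(NA_real_, length(keep))
  pw <- rep(NA_real_, length(keep))
  for (i in seq_along(keep)) {
    r <- keep[i]
    x <- bmat[r, ]; x <- x[!is.na(x)]
    if (nc[i] == 0) next  # SINQ path: no fold change can be formed
    y <- cobs[r, ]
    if (nc[i] >= nctot / 2) {
      y <- y[!is.na(y)]            # sporadic missingness: drop
    } else {
      y[is.na(y)] <- cimp[r, is.na(y)]  # widespread absence: impute low
    }
    d[i] <- mean(x) - mean(y)
    ss <- sum((x - mean(x))^2) + sum((y - mean(y))^2)
    df[i] <- length(x) + length(y) - 2
    s2[i] <- ss / df[i]
    ny[i] <- length(y)
    if (test == "welch") pw[i] <- .welch_p(x, y)
  }

  if (test == "moderated") {
    ok <- which(!is.na(s2) & df > 0)
    p <- rep(NA_real_, length(keep))
    if (length(ok)) {
      sq <- limma::squeezeVar(s2[ok], df[ok])
      se <- sqrt(sq$var.post * (1 / nb[ok] + 1 / ny[ok]))
      tt <- ifelse(se > 0, d[ok] / se,
                   ifelse(d[ok] == 0, 0, sign(d[ok]) * Inf))
      dft <- df[ok] + sq$df.prior
      p[ok] <- 2 * stats::pt(-abs(tt), dft)
    }
  } else {
    p <- pw
  }

  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], "BH")
  res <- data.frame(bait_id = bait, protein_acc = prot,
                    log2fc = d, p_value = p, q_value = q,
                    n_bait_obs = as.integer(nb),
                    n_ctrl_obs = as.integer(nc),
                    stringsAsFactors = FALSE)
  res[order(res$protein_acc), , drop = FALSE]
}

# accessor shared by QuantMatrix and NormalizedMatrix row space
qm_proteins_nm <- function(x) rownames(x$intensity)

#' Score every bait against its control group
#'
#' Applies [bscg_statistics()] to each bait in turn, sharing one seeded
#' imputation draw per missing cell so results are equivariant under
#' bait relabelling. No multiple-testing correction is applied to the
#' reported p-values (the HCIP criterion is raw p < 0.05); BH q-values
#' ride along as a column.
#'
#' @inheritParams bscg_statistics
#' @param baits baits to score; default all.
#' @return row-bound data frame of per-bait results, ordered by bait
#'   then protein.
#' @export
score_all_baits <- function(nm, baits = unique(nm$samples$bait_id),
                            test = c("moderated", "welch"),
                            eps = 1, seed = 1L) {
  test <- match.arg(test)
  ln <- log2(nm$intensity + eps)
  imputed <- .imputation_matrix(ln, seed)
  out <- lapply(sort(baits), function(b)
    bscg_statistics(nm, b, test = test, eps = eps, seed = seed,
                    imputed = imputed))
  do.call(rbind, out)
}
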