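#' Per-sample normalized spectral-index (SINQ) scores
#'
#' For each sample, every detected protein gets a spectral index — its
#' summed peptide intensity in that sample — and a SINQ score: the
#' spectral index divided by the sample total, then by the protein
#' length in residues. The score therefore satisfies, within each
#' sample, sum over detected proteins of `sinq_score * length` = 1.
#' When intensities are unavailable the spectral counts can stand in as
#' the index (`use_counts = TRUE`).
#'
#' @param qm a [quant_matrix()] (raw, unnormalized — the score is scale
#'   invariant within a sample by construction).
#' @param lengths named integer vector from [read_fasta_lengths()]; every
#'   detected protein must have an entry.
#' @param samples sample ids to score; default all.
#' @param use_counts use spectral counts instead of intensities as the
#'   spectral index.
#' @return data frame with columns `sample_id`, `protein_acc`,
#'   `spectral_index`, `sinq_score`, `spectral_count`, `detected`,
#'   covering detected proteins only.
#' @export
sinq_table <- function(qm, lengths, samples = qm$samples$sample_id,
                       use_counts = FALSE) {
  out <- vector("list", length(samples))
  for (k in seq_along(samples)) {
    s <- samples[k]
    if (!s %in% colnames(qm$intensity)) stop("unknown sample: ", s)
    sc <- qm$spectral_count[, s]
    det <- sc > 0
    if (!any(det)) {
      warning("sample ", s, " has no detected proteins")
      out[[k]] <- data.frame(sample_id = character(0),
                             protein_acc = character(0),
                             spectral_index = numeric(0),
                             sinq_score = numeric(0),
                             spectral_count = integer(0),
                             detected = logical(0))
      next
    }
    acc <- qm_proteins(qm)[det]
    nolen <- acc[!acc %in% names(lengths)]
    if (length(nolen))
      stop("detected protein(s) without a length entry: ",
           paste(utils::head(nolen, 3), collapse = ", "))
    si <- if (use_counts) as.numeric(sc[det]) else qm$intensity[det, s]
    score <- (si / sum(si)) / lengths[acc]
    out[[k]] <- data.frame(sample_id = s, protein_acc = acc,
                           spectral_index = si, sinq_score = unname(score),
                           spectral_count = sc[det], detected = TRUE,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Rescue bait-exclusive interactors by SINQ score
#'
#' Proteins detected with exactly one bait never acquire a fold change in
#' the comparative analysis (no control observations), so they are
#' rescued here: a protein detected in one bait's samples and zero
#' samples of every other bait is called an exclusive interactor when its
#' best per-sample SINQ score reaches `min_sinq` and its spectral counts,
#' summed over the bait's samples, exceed `min_sc`, and it is not a
#' contaminant. A bait's own accession is never its own exclusive.
#'
#' @param sinq a [sinq_table()] result covering all samples.
#' @param samples the experiment's sample sheet (`sample_id`, `bait_id`).
#' @param contaminants character vector of contaminant accessions.
#' @param min_sinq minimum per-sample SINQ score; default `1e-7`.
#' @param min_sc summed spectral counts must be strictly greater than
#'   this; default 1 (i.e. more than one spectrum).
#' @return data frame with columns `bait_id`, `protein_acc`, `max_sinq`,
#'   `total_spectral_count`.
#' @export
find_exclusives <- function(sinq, samples, contaminants = character(0),
                            min_sinq = 1e-7, min_sc = 1L) {
  stopifnot(min_sinq >= 0, min_sc >= 0)
  bait_of <- stats::setNames(samples$bait_id, samples$sample_id)
  sinq$bait_id <- bait_of[sinq$sample_id]
  nb <- tapply(sinq$bait_id, sinq$protein_acc,
               function(b) length(unique(b)))
  excl_prot <- names(nb)[nb == 1]
  sub <- sinq[sinq$protein_acc %in% excl_prot, , drop = FALSE]
  if (nrow(sub) == 0)
    return(data.frame(bait_id = character(0), protein_acc = character(0),
                      max_sinq = numeric(0),
                      total_spectral_count = integer(0)))
  key <- paste(sub$bait_id, sub$protein_acc, sep = "\r")
  agg <- data.frame(
    bait_id = tapply(sub$bait_id, key, `[`, 1),
    protein_acc = tapply(sub$protein_acc, key, `[`, 1),
    max_sinq = as.numeric(tapply(sub$sinq_score, key, max)),
    total_spectral_count = as.integer(tapply(sub$spectral_count, key, sum)),
    stringsAsFactors = FALSE)
  keep <- agg$max_sinq >= min_sinq &
    agg$total_spectral_count > min_sc &
    !(agg$protein_acc %in% contaminants) &
    agg$protein_acc != agg$bait_id
  res <- agg[keep, , drop = FALSE]
  res <- res[order(res$bait_id, res$protein_acc), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Per-bait spectral-count profile of one protein
#'
#' Sums a protein's spectral counts over each bait's samples and reports
#' the across-bait median (the reference line of a per-bait bar plot)
#' plus an upper-quartile membership flag per bait.
#'
#' @param qm a [quant_matrix()].
#' @param protein protein accession.
#' @return list with elements `counts` (named per-bait totals), `median`,
#'   and `upper_quartile` (named logical: count >= 75th percentile).
#' @export
spectral_count_profile <- function(qm, protein) {
  if (!protein %in% qm_proteins(qm))
    stop("protein not in quant matrix: ", protein)
  baits <- qm_baits(qm)
  counts <- vapply(baits, function(b)
    sum(qm$spectral_count[protein, qm$samples$bait_id == b]), 0)
  q3 <- stats::quantile(counts, 0.75, names = FALSE)
  list(counts = counts,
       median = stats::median(counts),
       upper_quartile = counts >= q3)
}
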