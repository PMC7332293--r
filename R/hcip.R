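#' Apply the four-criterion HCIP filter to comparative scoring results
#'
#' A bait-prey record is a high-confidence candidate interacting protein
#' (HCIP) when all of: (1) p-value below `alpha`; (2) strictly positive
#' log2 fold change; (3) at least `min_unique_peptides` distinct peptide
#' sequences for the prey within the bait's samples; (4) the prey is not
#' a common contaminant. A bait's own accession is additionally excluded
#' from the edge list (its pull-down of itself is kept separately as the
#' bait's raw abundance).
#'
#' Every scored record is returned with a `passed_filters` flag; the
#' downstream network uses the passing subset.
#'
#' @param bscg result of [score_all_baits()].
#' @param qm the [quant_matrix()] the scores came from (supplies
#'   unique-peptide counts).
#' @param contaminants character vector of contaminant accessions.
#' @param alpha p-value cutoff; default 0.05.
#' @param min_unique_peptides default 2.
#' @param sinq optional [sinq_table()] result; when given, each record is
#'   annotated with the prey's best SINQ score across the bait's samples.
#' @return data frame of HCIP records: `bait_id`, `protein_acc`,
#'   `provenance` (`"bscg"`), `p_value`, `q_value`, `log2fc`,
#'   `unique_peptides`, `sinq_score`, `n_bait_obs`, `n_ctrl_obs`,
#'   `passed_filters`.
#' @export
call_hcips <- function(bscg, qm, contaminants = character(0),
                       alpha = 0.05, min_unique_peptides = 2L,
                       sinq = NULL) {
  stopifnot(alpha > 0, alpha < 1, min_unique_peptides >= 0)
  up <- qm$unique_peptides[cbind(match(bscg$protein_acc, qm_proteins(qm)),
                                 match(bscg$bait_id,
                                       colnames(qm$unique_peptides)))]
  sq <- rep(NA_real_, nrow(bscg))
  if (!is.null(sinq)) {
    bait_of <- stats::setNames(qm$samples$bait_id, qm$samples$sample_id)
    skey <- paste(bait_of[sinq$sample_id], sinq$protein_acc, sep = "\r")
    best <- tapply(sinq$sinq_score, skey, max)
    sq <- as.numeric(best[paste(bscg$bait_id, bscg$protein_acc,
                                sep = "\r")])
  }
  passed <- !is.na(bscg$p_value) & bscg$p_value < alpha &
    !is.na(bscg$log2fc) & bscg$log2fc > 0 &
    up >= min_unique_peptides &
    !(bscg$protein_acc %in% contaminants) &
    bscg$protein_acc != bscg$bait_id
  res <- data.frame(bait_id = bscg$bait_id,
                    protein_acc = bscg$protein_acc,
                    provenance = "bscg",
                    p_value = bscg$p_value, q_value = bscg$q_value,
                    log2fc = bscg$log2fc,
                    unique_peptides = as.integer(up),
                    sinq_score = sq,
                    n_bait_obs = bscg$n_bait_obs,
                    n_ctrl_obs = bscg$n_ctrl_obs,
                    passed_filters = passed,
                    stringsAsFactors = FALSE)
  res[order(res$bait_id, res$protein_acc), , drop = FALSE]
}

#' Merge comparative calls with SINQ-exclusive rescues
#'
#' Union keyed on (bait, prey). Where a pair was actually scored by the
#' comparative route (it has a p-value), that record wins and its
#' provenance stays `bscg`. A comparative record that could not be
#' scored (`p_value` missing with `n_ctrl_obs = 0` — the very records
#' the rescue exists for) is upgraded in place: provenance becomes
#' `sinq_exclusive`, the SINQ score is attached and `passed_filters`
#' set. Exclusives absent from the table enter as new records with no
#' p-value or fold change (none can be formed). Merging is idempotent.
#'
#' @param bscg_calls result of [call_hcips()].
#' @param exclusives result of [find_exclusives()].
#' @param qm optional [quant_matrix()] to fill unique-peptide counts of
#'   exclusive records.
#' @return merged HCIP record data frame, ordered by bait then prey.
#' @export
merge_hcips <- function(bscg_calls, exclusives, qm = NULL) {
  if (nrow(exclusives) == 0) return(bscg_calls)
  have <- paste(bscg_calls$bait_id, bscg_calls$protein_acc, sep = "\r")
  ekey <- paste(exclusives$bait_id, exclusives$protein_acc, sep = "\r")

  # upgrade unscoreable comparative records the rescue re-identified
  up_i <- match(ekey, have)
  upgrade <- !is.na(up_i) & is.na(bscg_calls$p_value[up_i]) &
    bscg_calls$provenance[up_i] == "bscg"
  if (any(upgrade)) {
    ri <- up_i[upgrade]
    bscg_calls$provenance[ri] <- "sinq_exclusive"
    bscg_calls$sinq_score[ri] <- exclusives$max_sinq[upgrade]
    bscg_calls$passed_filters[ri] <- TRUE
  }

  new <- exclusives[is.na(up_i), , drop = FALSE]
  if (nrow(new) == 0) {
    rownames(bscg_calls) <- NULL
    return(bscg_calls)
  }
  up <- rep(NA_integer_, nrow(new))
  if (!is.null(qm))
    up <- as.integer(qm$unique_peptides[
      cbind(match(new$protein_acc, qm_proteins(qm)),
            match(new$bait_id, colnames(qm$unique_peptides)))])
  add <- data.frame(bait_id = new$bait_id, protein_acc = new$protein_acc,
                    provenance = "sinq_exclusive",
                    p_value = NA_real_, q_value = NA_real_,
                    log2fc = NA_real_,
                    unique_peptides = up,
                    sinq_score = new$max_sinq,
                    n_bait_obs = NA_integer_, n_ctrl_obs = 0L,
                    passed_filters = TRUE,
                    stringsAsFactors = FALSE)
  out <- rbind(bscg_calls, add)
  out <- out[order(out$bait_id, out$protein_acc), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the bait-prey interaction network
#'
#' Collects the passing HCIP records into an edge set and computes the
#' per-bait call counts, per-prey degrees (number of distinct baits
#' calling each prey) and each bait's raw abundance — the summed raw
#' intensity of the bait's own accession across its own samples, the
#' self-pull-down signal excluded from the edge list.
#'
#' @param hcips merged HCIP record data frame.
#' @param qm the [quant_matrix()].
#' @return object of class `InteractionNetwork`: `edges` (data frame),
#'   `bait_counts`, `prey_degree`, `raw_abundance` (all named vectors).
#' @export
build_network <- function(hcips, qm) {
  passed <- hcips[hcips$passed_filters, , drop = FALSE]
  baits <- qm_baits(qm)
  bait_counts <- stats::setNames(
    vapply(baits, function(b) sum(passed$bait_id == b), 0L), baits)
  prey_degree <- if (nrow(passed))
    vapply(split(passed$bait_id, passed$protein_acc),
           function(b) length(unique(b)), 0L) else
    stats::setNames(integer(0), character(0))
  raw_abundance <- stats::setNames(vapply(baits, function(b) {
    if (!b %in% qm_proteins(qm)) return(0)
    sum(qm$intensity[b, qm$samples$bait_id == b], na.rm = TRUE)
  }, 0), baits)
  structure(list(edges = passed[, c("bait_id", "protein_acc",
                                    "provenance", "p_value", "log2fc",
                                    "sinq_score")],
                 bait_counts = bait_counts,
                 prey_degree = prey_degree,
                 raw_abundance = raw_abundance),
            class = "InteractionNetwork")
}

#' @export
print.InteractionNetwork <- function(x, ...) {
  cat(sprintf("InteractionNetwork: %d edges, %d baits, %d distinct preys\n",
              nrow(x$edges), length(x$bait_counts), length(x$prey_degree)))
  invisible(x)
}

#' Prey-sharing distribution
#'
#' How many preys are called by exactly one bait (candidate specific
#' cofactors or substrates), two, three, or four and more (shared
#' machinery)? The histogram sums to the number of distinct preys.
#'
#' @param net an [build_network()] result.
#' @return named integer vector with bins `"1"`, `"2"`, `"3"`, `">=4"`.
#' @export
sharing_distribution <- function(net) {
  deg <- net$prey_degree
  c("1" = sum(deg == 1), "2" = sum(deg == 2), "3" = sum(deg == 3),
    ">=4" = sum(deg >= 4))
}

#' Correlation of bait abundance with HCIP count
#'
#' Pearson correlation, across baits, between each bait's raw abundance
#' (self-pull-down intensity) and the number of HCIPs it was assigned —
#' a check that interaction counts reflect bait biology rather than
#' expression level.
#'
#' @param net an [build_network()] result.
#' @return list with `r` (Pearson coefficient, `NA` with a warning when
#'   either variable has zero variance), `n_baits`, and the two vectors.
#' @export
abundance_hcip_correlation <- function(net) {
  ra <- net$raw_abundance
  ct <- as.numeric(net$bait_counts[names(ra)])
  if (length(ra) < 3) stop("correlation needs >= 3 baits")
  if (stats::sd(ra) == 0 || stats::sd(ct) == 0) {
    warning("zero variance; Pearson correlation undefined")
    r <- NA_real_
  } else r <- stats::cor(ra, ct)
  list(r = r, n_baits = length(ra), raw_abundance = ra, hcip_counts = ct)
}

#' Classify preys as ER/membrane or soluble
#'
#' A prey is assigned to the ER/membrane (secretory-pathway) class when
#' any of its annotation flags — transmembrane domain, signal peptide,
#' N-glycosylation, disulphide bond — is set; to the soluble class when
#' all are present and false; preys absent from the annotation table are
#' reported as `unknown`, never silently assumed soluble, and excluded
#' from the fraction.
#'
#' @param hcips merged HCIP record data frame.
#' @param annotations a [read_annotations()]-style data frame.
#' @return list: `classes` (data frame `protein_acc`, `class`) over the
#'   distinct passing preys, and `fraction_er` among annotated preys.
#' @export
classify_secretory <- function(hcips, annotations) {
  preys <- sort(unique(hcips$protein_acc[hcips$passed_filters]))
  i <- match(preys, annotations$protein_acc)
  flags <- annotations[i, c("has_tmd", "has_signal_peptide", "has_nglyc",
                            "has_disulphide")]
  any_flag <- rowSums(flags, na.rm = FALSE) > 0
  cls <- ifelse(is.na(i), "unknown",
                ifelse(any_flag, "ER/membrane", "soluble"))
  known <- cls != "unknown"
  list(classes = data.frame(protein_acc = preys, class = cls,
                            stringsAsFactors = FALSE),
       fraction_er = if (any(known))
         sum(cls == "ER/membrane") / sum(known) else NA_real_)
}

#' Overlap of called interactions with a prior-knowledge edge list
#'
#' An HCIP edge counts as previously known when its unordered accession
#' pair appears in the prior edge list (e.g. a public interaction
#' database snapshot).
#'
#' @param hcips merged HCIP record data frame.
#' @param prior_edges data frame `protein_a`, `protein_b` (undirected).
#' @return list: `edges` (bait, prey, `known` flag), `n_known`,
#'   `n_total`, `fraction`.
#' @export
known_overlap <- function(hcips, prior_edges) {
  passed <- hcips[hcips$passed_filters, , drop = FALSE]
  norm_pair <- function(a, b)
    paste(pmin(a, b), pmax(a, b), sep = "\r")
  prior <- unique(norm_pair(prior_edges$protein_a, prior_edges$protein_b))
  known <- norm_pair(passed$bait_id, passed$protein_acc) %in% prior
  list(edges = data.frame(bait_id = passed$bait_id,
                          protein_acc = passed$protein_acc,
                          known = known, stringsAsFactors = FALSE),
       n_known = sum(known), n_total = nrow(passed),
       fraction = if (nrow(passed)) sum(known) / nrow(passed) else NA_real_)
}

#' Hierarchically clustered bait x prey p-value matrix
#'
#' Builds the matrix of -log10 p-values over passing records (cells with
#' no record, or records without a p-value such as SINQ exclusives, are
#' 0) and orders both axes by average-linkage hierarchical clustering of
#' Euclidean distances — the layout of an interactome heat map.
#'
#' @param hcips merged HCIP record data frame.
#' @param linkage agglomeration method for [stats::hclust()].
#' @param metric distance for [stats::dist()].
#' @return list: `matrix` (clustered order), `bait_order`, `prey_order`
#'   (leaf orders as names).
#' @export
cluster_pvalue_heatmap <- function(hcips, linkage = "average",
                                   metric = "euclidean") {
  passed <- hcips[hcips$passed_filters, , drop = FALSE]
  baits <- sort(unique(passed$bait_id))
  preys <- sort(unique(passed$protein_acc))
  M <- matrix(0, length(baits), length(preys),
              dimnames = list(baits, preys))
  pv <- passed$p_value
  val <- ifelse(is.na(pv), 0, -log10(pmax(pv, .Machine$double.xmin)))
  M[cbind(match(passed$bait_id, baits),
          match(passed$protein_acc, preys))] <- val
  bait_order <- baits
  prey_order <- preys
  if (length(baits) >= 2 && length(preys) >= 2) {
    bait_order <- baits[stats::hclust(stats::dist(M, method = metric),
                                      method = linkage)$order]
    prey_order <- preys[stats::hclust(stats::dist(t(M), method = metric),
                                      method = linkage)$order]
  } else {
    warning("fewer than 2 baits or preys; returning input order")
  }
  list(matrix = M[bait_order, prey_order, drop = FALSE],
       bait_order = bait_order, prey_order = prey_order)
}
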