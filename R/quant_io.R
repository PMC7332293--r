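#' Construct a QuantMatrix
#'
#' The central container of the package: protein-level intensities and
#' spectral counts for a multi-bait AP-MS experiment, together with the
#' sample annotation (which bait each purified sample belongs to) and the
#' per-(protein, bait) unique-peptide counts used by the HCIP filter.
#'
#' Missing cells are represented explicitly as `NA` in the intensity grid,
#' never as 0, so downstream statistics can choose their own handling. A
#' cell is missing if and only if its spectral count is 0.
#'
#' @param intensity numeric matrix, proteins x samples; `NA` marks a
#'   protein undetected in a sample. Non-missing values must be >= 0.
#' @param spectral_count integer matrix of the same shape; 0 exactly where
#'   `intensity` is `NA`.
#' @param unique_peptides integer matrix, proteins x baits: number of
#'   distinct peptide sequences of each protein detected in any sample of
#'   each bait.
#' @param samples data frame with columns `sample_id`, `bait_id`,
#'   `replicate` (and optionally `is_control_only`), one row per sample,
#'   in the column order of the matrices.
#' @return An object of class `QuantMatrix`.
#' @export
quant_matrix <- function(intensity, spectral_count, unique_peptides, samples) {
  stopifnot(is.matrix(intensity), is.matrix(spectral_count))
  if (!all(dim(intensity) == dim(spectral_count)))
    stop("intensity and spectral_count grids differ in shape")
  if (is.null(rownames(intensity)))
    stop("intensity must carry protein accessions as rownames")
  if (!identical(colnames(intensity), samples$sample_id))
    stop("matrix column order must match the sample sheet")
  req <- c("sample_id", "bait_id", "replicate")
  if (!all(req %in% names(samples)))
    stop("sample sheet needs columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in sample sheet")
  if (any(samples$replicate < 1))
    stop("replicate indices must be >= 1")
  if (!("is_control_only" %in% names(samples)))
    samples$is_control_only <- FALSE
  if (any(intensity[!is.na(intensity)] < 0))
    stop("negative intensity")
  miss <- is.na(intensity)
  if (any(spectral_count[miss] != 0))
    stop("missing intensity cells must have spectral_count 0")
  if (any(spectral_count[!miss] == 0))
    stop("cells with spectral_count 0 must be marked missing (NA intensity)")
  baits <- unique(samples$bait_id)
  if (is.null(unique_peptides)) {
    unique_peptides <- matrix(0L, nrow(intensity), length(baits),
                              dimnames = list(rownames(intensity), baits))
  }
  if (!identical(sort(colnames(unique_peptides)), sort(baits)))
    stop("unique_peptides columns must be the bait ids")
  structure(
    list(intensity = intensity,
         spectral_count = spectral_count,
         unique_peptides = unique_peptides[, baits, drop = FALSE],
         samples = samples[, c(req, "is_control_only")]),
    class = "QuantMatrix")
}

#' @export
print.QuantMatrix <- function(x, ...) {
  cat(sprintf("QuantMatrix: %d proteins x %d samples (%d baits), %.1f%% missing\n",
              nrow(x$intensity), ncol(x$intensity),
              length(unique(x$samples$bait_id)),
              100 * mean(is.na(x$intensity))))
  invisible(x)
}

#' Protein accessions of a QuantMatrix
#' @param qm a `QuantMatrix`.
#' @return character vector of accessions, in matrix row order.
#' @export
qm_proteins <- function(qm) rownames(qm$intensity)

#' Bait identifiers of a QuantMatrix
#' @param qm a `QuantMatrix`.
#' @return character vector of bait ids, in sample-sheet order.
#' @export
qm_baits <- function(qm) unique(qm$samples$bait_id)

# shared delimiter sniffing: tab wins over comma if both present in header
.sniff_sep <- function(path) {
  con <- file(path, "rt"); on.exit(close(con))
  hdr <- readLines(con, n = 1L)
  if (grepl("\t", hdr)) "\t" else ","
}

#' Read a peptide-level quantification table into a QuantMatrix
#'
#' Consumes a Progenesis-style export rolled out wide: columns `protein`,
#' `peptide`, then per-sample paired columns `<sample_id>.intensity` and
#' `<sample_id>.sc`. Delimiter (tab or comma) is auto-detected and gzipped
#' files are read transparently. Peptide rows are aggregated to protein
#' level by summing intensities and spectral counts per (protein, sample);
#' a protein-sample cell with total spectral count 0 is marked missing.
#' `unique_peptides[p, b]` counts the distinct peptide sequences of `p`
#' detected (spectral count > 0) in any sample of bait `b`.
#'
#' @param path quantification table (TSV/CSV, optionally `.gz`).
#' @param sample_sheet TSV with columns `sample_id`, `bait_id`,
#'   `replicate`, declaring every sample column of the table.
#' @return A [quant_matrix()].
#' @export
read_quant_table <- function(path, sample_sheet) {
  if (!file.exists(path)) stop("quant table not found: ", path)
  if (!file.exists(sample_sheet)) stop("sample sheet not found: ", sample_sheet)
  sheet <- utils::read.delim(sample_sheet, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "bait_id", "replicate") %in% names(sheet)))
    stop("sample sheet needs columns sample_id, bait_id, replicate")
  sheet$sample_id <- as.character(sheet$sample_id)
  sheet$bait_id <- as.character(sheet$bait_id)

  sep <- .sniff_sep(path)
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "")
  if (!all(c("protein", "peptide") %in% names(tab)))
    stop("quant table must have 'protein' and 'peptide' columns")
  datacols <- setdiff(names(tab), c("protein", "peptide"))
  m <- regmatches(datacols, regexec("^(.*)\\.(intensity|sc)$", datacols))
  bad <- datacols[vapply(m, length, 1L) == 0]
  if (length(bad))
    stop("unrecognised column(s) in quant table: ", paste(bad, collapse = ", "))
  col_sample <- vapply(m, `[`, "", 2L)
  unknown <- setdiff(unique(col_sample), sheet$sample_id)
  if (length(unknown))
    stop("sample column(s) not declared in sample sheet: ",
         paste(unknown, collapse = ", "))
  absent <- setdiff(sheet$sample_id, unique(col_sample))
  if (length(absent))
    stop("sample(s) declared in sheet but absent from table: ",
         paste(absent, collapse = ", "))
  for (s in sheet$sample_id)
    for (suf in c("intensity", "sc"))
      if (!(paste0(s, ".", suf) %in% datacols))
        stop("missing column ", paste0(s, ".", suf))

  .aggregate_quant(tab, sheet)
}

# Peptide-to-protein roll-up shared by read_quant_table() and the
# simulator: plain summation of intensities and spectral counts per
# (protein, sample); a protein-sample cell is missing iff its summed
# spectral count is 0; unique_peptides counts distinct detected peptide
# sequences per (protein, bait).
.aggregate_quant <- function(tab, sheet) {
  key <- paste(tab$protein, tab$peptide, sep = "\r")
  if (anyDuplicated(key))
    stop("aggregation conflict: duplicate (protein, peptide) rows for ",
         paste(utils::head(tab$protein[duplicated(key)], 3), collapse = ", "))
  if (any(tab$peptide == "")) stop("empty peptide sequence")

  prots <- sort(unique(tab$protein))
  pf <- factor(tab$protein, levels = prots)
  nS <- nrow(sheet)
  intensity <- matrix(NA_real_, length(prots), nS,
                      dimnames = list(prots, sheet$sample_id))
  sc <- matrix(0L, length(prots), nS, dimnames = list(prots, sheet$sample_id))
  det_pep <- matrix(FALSE, nrow(tab), nS)  # peptide-row x sample detection
  for (j in seq_len(nS)) {
    s <- sheet$sample_id[j]
    iv <- tab[[paste0(s, ".intensity")]]
    cv <- tab[[paste0(s, ".sc")]]
    iv[is.na(iv)] <- 0
    cv[is.na(cv)] <- 0L
    if (any(iv < 0)) stop("negative intensity in sample ", s)
    det <- cv > 0  # spectral_count 0 => intensity treated as missing
    det_pep[, j] <- det
    tot_i <- rowsum(ifelse(det, iv, 0), pf)[, 1]
    tot_c <- rowsum(as.integer(cv), pf)[, 1]
    obs <- tot_c > 0
    intensity[obs, j] <- tot_i[obs]
    sc[, j] <- as.integer(tot_c)
  }

  baits <- unique(sheet$bait_id)
  up <- matrix(0L, length(prots), length(baits),
               dimnames = list(prots, baits))
  for (b in baits) {
    cols <- which(sheet$bait_id == b)
    det_b <- rowSums(det_pep[, cols, drop = FALSE]) > 0
    if (any(det_b)) {
      cnt <- tapply(tab$peptide[det_b], droplevels(pf[det_b]),
                    function(x) length(unique(x)))
      up[names(cnt), b] <- as.integer(cnt)
    }
  }
  quant_matrix(intensity, sc, up, sheet)
}

#' Read protein sequence lengths from a FASTA file
#'
#' Accessions are taken as the first whitespace-delimited header token; a
#' UniProt-style `db|ACC|NAME` token is reduced to `ACC`. Duplicate
#' records with equal lengths collapse silently; unequal lengths are an
#' error.
#'
#' @param path FASTA file.
#' @return named integer vector: accession -> sequence length (residues).
#' @export
read_fasta_lengths <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) stop("no FASTA records in ", path)
  if (any(Biostrings::width(seqs) == 0))
    stop("empty sequence for record(s): ",
         paste(utils::head(names(seqs)[Biostrings::width(seqs) == 0], 3),
               collapse = ", "))
  tok <- sub("\\s.*$", "", names(seqs))
  piped <- grepl("^[^|]+\\|[^|]+\\|", tok)
  tok[piped] <- vapply(strsplit(tok[piped], "|", fixed = TRUE),
                       `[`, "", 2L)
  if (any(tok == "")) stop("unparsable FASTA header")
  len <- Biostrings::width(seqs)
  out <- integer(0)
  for (i in seq_along(tok)) {
    a <- tok[i]
    if (a %in% names(out)) {
      if (out[[a]] != len[i])
        stop("duplicate accession ", a, " with unequal lengths")
    } else out[[a]] <- len[i]
  }
  out
}

#' Read a contaminant accession list
#'
#' One accession per line; `#` starts a comment; blank lines ignored;
#' case preserved. An empty result triggers a warning (contaminant
#' filtering then is a no-op) but is valid.
#'
#' @param path plain-text file.
#' @return character vector of unique accessions.
#' @export
read_contaminant_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  acc <- unique(lines[nzchar(lines)])
  if (length(acc) == 0)
    warning("contaminant list ", path, " is empty")
  acc
}

#' Read a protein feature annotation table
#'
#' TSV with columns `protein_acc`, `length_aa`, `has_tmd`,
#' `has_signal_peptide`, `has_nglyc`, `has_disulphide`; the flags are
#' logical (TRUE/FALSE or 0/1). Used by [classify_secretory()].
#'
#' @param path TSV file.
#' @return data frame, one row per protein.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_acc", "length_aa", "has_tmd", "has_signal_peptide",
            "has_nglyc", "has_disulphide")
  if (!all(need %in% names(ann)))
    stop("annotation table needs columns: ", paste(need, collapse = ", "))
  for (f in need[-(1:2)]) ann[[f]] <- as.logical(ann[[f]])
  if (any(ann$length_aa < 1)) stop("length_aa must be >= 1")
  ann
}

#' Read a prior-interaction edge list
#'
#' Undirected edges, TSV columns `protein_a`, `protein_b` (a snapshot of
#' a public interaction resource). Used by [known_overlap()].
#'
#' @param path TSV file.
#' @return data frame with columns `protein_a`, `protein_b`.
#' @export
read_prior_edges <- function(path) {
  pe <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("protein_a", "protein_b") %in% names(pe)))
    stop("prior edge list needs columns protein_a, protein_b")
  pe[, c("protein_a", "protein_b")]
}

# format numerics so that write-then-read reproduces doubles exactly
.fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))

.hcip_num_cols <- c("p_value", "q_value", "log2fc", "sinq_score")

#' Write pipeline outputs
#'
#' Writes `hcips.tsv` (every scored record with all filter fields),
#' `edges.tsv` (bait, prey, provenance, p-value, log2fc, SINQ score for
#' records that passed the filters) and `summary.json` (per-bait counts,
#' prey-sharing histogram, overlap statistics when available, and the
#' exact thresholds and seed used). Row order is deterministic: bait,
#' then prey, lexicographic. Numerics are written with full precision so
#' [read_hcips()] round-trips exactly.
#'
#' @param hcips data frame of HCIP records (see [call_hcips()]).
#' @param out_dir output directory, created if needed.
#' @param network optional result of [build_network()].
#' @param overlap optional result of [known_overlap()].
#' @param provenance optional named list of thresholds/seed to record.
#' @return invisibly, the paths written.
#' @export
write_outputs <- function(hcips, out_dir, network = NULL, overlap = NULL,
                          provenance = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  ord <- order(hcips$bait_id, hcips$protein_acc)
  hcips <- hcips[ord, , drop = FALSE]

  h <- hcips
  for (cc in intersect(.hcip_num_cols, names(h))) h[[cc]] <- .fmt_num(h[[cc]])
  f_hcips <- file.path(out_dir, "hcips.tsv")
  utils::write.table(h, f_hcips, sep = "\t", quote = FALSE, row.names = FALSE)

  passed <- hcips[hcips$passed_filters, , drop = FALSE]
  ed <- data.frame(bait = passed$bait_id, prey = passed$protein_acc,
                   provenance = passed$provenance,
                   p_value = .fmt_num(passed$p_value),
                   log2fc = .fmt_num(passed$log2fc),
                   sinq = .fmt_num(passed$sinq_score),
                   stringsAsFactors = FALSE)
  f_edges <- file.path(out_dir, "edges.tsv")
  utils::write.table(ed, f_edges, sep = "\t", quote = FALSE, row.names = FALSE)

  counts <- if (nrow(passed)) as.list(table(passed$bait_id)) else
    stats::setNames(list(), character(0))
  summ <- list(n_records = nrow(hcips), n_hcips = nrow(passed),
               hcips_per_bait = counts)
  if (!is.null(network))
    summ$sharing_histogram <- as.list(sharing_distribution(network))
  if (!is.null(overlap))
    summ$overlap <- list(known = overlap$n_known, total = overlap$n_total,
                         fraction = overlap$fraction)
  if (!is.null(provenance)) summ$provenance <- provenance
  f_sum <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summ, f_sum, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(f_hcips, f_edges, f_sum))
}

#' Read back an hcips.tsv written by write_outputs
#' @param path path to `hcips.tsv`.
#' @return data frame of HCIP records, numerically identical to what was
#'   written.
#' @export
read_hcips <- function(path) {
  h <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (cc in intersect(.hcip_num_cols, names(h)))
    h[[cc]] <- as.numeric(h[[cc]])
  if ("passed_filters" %in% names(h))
    h$passed_filters <- as.logical(h$passed_filters)
  h
}
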