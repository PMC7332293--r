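# Fixture builders shared across test files. Everything is constructed in
# code; nothing is read from stored data.

# A small QuantMatrix built directly from matrices. `log2_intensity` may
# contain NA (missing); spectral counts default to 3 where detected.
make_qm <- function(log2_intensity, baits, replicates = NULL,
                    unique_peptides = NULL, spectral_count = NULL) {
  intensity <- 2^log2_intensity
  n <- ncol(intensity)
  if (is.null(replicates)) {
    replicates <- stats::ave(seq_len(n), baits, FUN = seq_along)
  }
  samples <- data.frame(
    sample_id = if (!is.null(colnames(intensity))) colnames(intensity) else
      sprintf("%s_r%d", baits, replicates),
    bait_id = baits, replicate = replicates, stringsAsFactors = FALSE)
  colnames(intensity) <- samples$sample_id
  if (is.null(spectral_count)) {
    spectral_count <- matrix(3L, nrow(intensity), n)
    spectral_count[is.na(intensity)] <- 0L
  }
  dimnames(spectral_count) <- dimnames(intensity)
  if (!is.null(unique_peptides) && is.null(colnames(unique_peptides)))
    colnames(unique_peptides) <- unique(baits)
  quant_matrix(intensity, spectral_count, unique_peptides, samples)
}

# Wrap an intensity matrix as an (already normalized) NormalizedMatrix so
# the statistics layer can be tested on exact values.
make_nm <- function(qm) {
  structure(list(intensity = qm$intensity,
                 scale_factors = stats::setNames(
                   rep(1, ncol(qm$intensity)), colnames(qm$intensity)),
                 samples = qm$samples,
                 unique_peptides = qm$unique_peptides,
                 spectral_count = qm$spectral_count,
                 background = rownames(qm$intensity)),
            class = "NormalizedMatrix")
}

# Write a peptide-level quant table + sample sheet in the input dialect.
write_quant_fixture <- function(tab, sheet,
                                dir = withr::local_tempdir(
                                  .local_envir = parent.frame()),
                                sep = "\t") {
  qt <- file.path(dir, if (sep == "\t") "quant.tsv" else "quant.csv")
  ss <- file.path(dir, "samples.tsv")
  utils::write.table(tab, qt, sep = sep, quote = FALSE, row.names = FALSE)
  utils::write.table(sheet, ss, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(quant = qt, samples = ss)
}

# An HCIP record data frame row (defaults pass every filter).
hcip_row <- function(bait = "B1", prot = "P1", provenance = "bscg",
                     p = 0.01, q = NA_real_, lfc = 2, up = 3L,
                     sinq = NA_real_, nb = 2L, nc = 40L, passed = TRUE) {
  data.frame(bait_id = bait, protein_acc = prot, provenance = provenance,
             p_value = p, q_value = q, log2fc = lfc,
             unique_peptides = up, sinq_score = sinq,
             n_bait_obs = nb, n_ctrl_obs = nc, passed_filters = passed,
             stringsAsFactors = FALSE)
}
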