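#' Configuration for the synthetic multi-bait AP-MS generator
#'
#' Defaults emulate a 21-bait panel purified in parallel with two
#' technical duplicates per bait over a shared background proteome:
#' 400 background proteins, 8 spiked interactors and 2 bait-exclusive
#' preys per bait, 30 ubiquitous contaminants, log2 enrichment effects
#' drawn from Uniform(2, 6), and 25% coefficient of variation on
#' intensities. Detection is intensity dependent (logistic in log2
#' intensity), so low-abundance cells go missing more often — the
#' mechanism the control-group imputation has to cope with.
#'
#' @param n_baits number of baits.
#' @param n_replicates technical duplicates per bait.
#' @param n_background background-proteome size.
#' @param n_interactors_per_bait spiked (enriched-everywhere-detected)
#'   preys per bait.
#' @param n_exclusive_per_bait preys generated only in the cognate
#'   bait's samples.
#' @param n_contaminants ubiquitous high-abundance contaminants.
#' @param log2_effect_range `c(low, high)` of the per-prey enrichment
#'   effect, log2 units.
#' @param background_log2_mean_sd `c(mu, sigma)` of per-protein base
#'   log2 intensities.
#' @param noise_cv per-cell intensity coefficient of variation; the
#'   log2 noise sd is `log2(1 + noise_cv)`.
#' @param detection_midpoint log2 intensity at 50% detection
#'   probability.
#' @param detection_scale logistic scale of the detection curve.
#' @param prey_two_peptide_prob probability that a spiked or exclusive
#'   prey's peptide repertoire is forced to >= 2 distinct sequences
#'   (so it can satisfy the unique-peptide criterion).
#' @param seed integer seed; the whole experiment is a deterministic
#'   function of it.
#' @return validated list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_baits = 21L, n_replicates = 2L,
                              n_background = 400L,
                              n_interactors_per_bait = 8L,
                              n_exclusive_per_bait = 2L,
                              n_contaminants = 30L,
                              log2_effect_range = c(2, 6),
                              background_log2_mean_sd = c(20, 2),
                              noise_cv = 0.25,
                              detection_midpoint = 13,
                              detection_scale = 1.5,
                              prey_two_peptide_prob = 0.95,
                              seed = 1L) {
  cfg <- list(n_baits = as.integer(n_baits),
              n_replicates = as.integer(n_replicates),
              n_background = as.integer(n_background),
              n_interactors_per_bait = as.integer(n_interactors_per_bait),
              n_exclusive_per_bait = as.integer(n_exclusive_per_bait),
              n_contaminants = as.integer(n_contaminants),
              log2_effect_range = as.numeric(log2_effect_range),
              background_log2_mean_sd = as.numeric(background_log2_mean_sd),
              noise_cv = as.numeric(noise_cv),
              detection_midpoint = as.numeric(detection_midpoint),
              detection_scale = as.numeric(detection_scale),
              prey_two_peptide_prob = as.numeric(prey_two_peptide_prob),
              seed = as.integer(seed))
  counts <- cfg[c("n_baits", "n_replicates", "n_background",
                  "n_interactors_per_bait", "n_exclusive_per_bait",
                  "n_contaminants")]
  if (any(unlist(counts) < 0)) stop("counts must be >= 0")
  if (cfg$n_baits < 2 || cfg$n_replicates < 1)
    stop("need >= 2 baits and >= 1 replicate")
  if (cfg$noise_cv <= 0) stop("noise_cv must be > 0")
  if (diff(cfg$log2_effect_range) < 0)
    stop("log2_effect_range must be (low, high) with low <= high")
  if (cfg$background_log2_mean_sd[2] <= 0) stop("sigma must be > 0")
  structure(cfg, class = "SimulationConfig")
}

.rand_peptide <- function(n, len_range = c(8L, 18L)) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(seq_len(n), function(i)
    paste(sample(aa, sample(len_range[1]:len_range[2], 1),
                 replace = TRUE), collapse = ""), "")
}

#' Simulate a multi-bait AP-MS experiment with known ground truth
#'
#' Generates per-protein base log2 intensities, adds the spiked
#' enrichment effect in each prey's cognate bait, cell-level log-normal
#' noise, intensity-dependent logistic detection (undetected cells are
#' missing with spectral count 0), spectral counts `1 + Poisson(I /
#' kappa)` with `kappa = 2^(mu - 1)` so the background median spectral
#' count is about 3, protein lengths Uniform{100..1500}, and a peptide
#' repertoire per protein whose per-sample detection makes
#' unique-peptide counts rise with intensity. Bait proteins themselves
#' are generated at high abundance only in their own samples
#' (self-pull-down). Everything is a deterministic function of
#' `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return list: `quant` ([quant_matrix()]), `peptides` (the wide
#'   peptide-level table in the dialect [read_quant_table()] reads),
#'   `sample_sheet`, `lengths` (named vector), `contaminants`
#'   (accessions), `truth` (data frame `protein_acc`, `role`,
#'   `bait_id`, `true_log2_effect`), and `config`.
#' @export
simulate_apms <- function(config = simulation_config()) {
  stopifnot(inherits(config, "SimulationConfig"))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  mu <- config$background_log2_mean_sd[1]
  sig <- config$background_log2_mean_sd[2]
  sdn <- log2(1 + config$noise_cv)
  kappa <- 2^(mu - 1)

  baits <- sprintf("BAIT%02d", seq_len(config$n_baits))
  sheet <- data.frame(
    sample_id = as.vector(t(outer(baits, seq_len(config$n_replicates),
                                  function(b, r) sprintf("%s_r%d", b, r)))),
    bait_id = rep(baits, each = config$n_replicates),
    replicate = rep(seq_len(config$n_replicates), config$n_baits),
    stringsAsFactors = FALSE)

  bg <- sprintf("BG%04d", seq_len(config$n_background))
  int <- if (config$n_interactors_per_bait > 0)
    sprintf("INT%04d", seq_len(config$n_baits *
                               config$n_interactors_per_bait)) else character(0)
  exc <- if (config$n_exclusive_per_bait > 0)
    sprintf("EXC%04d", seq_len(config$n_baits *
                               config$n_exclusive_per_bait)) else character(0)
  con <- if (config$n_contaminants > 0)
    sprintf("CON%03d", seq_len(config$n_contaminants)) else character(0)
  prots <- c(baits, bg, int, exc, con)

  role <- c(rep("bait", length(baits)), rep("background", length(bg)),
            rep("interactor", length(int)), rep("exclusive", length(exc)),
            rep("contaminant", length(con)))
  cognate <- rep(NA_character_, length(prots))
  cognate[role == "bait"] <- baits
  cognate[role == "interactor"] <- rep(baits,
                                       each = config$n_interactors_per_bait)
  cognate[role == "exclusive"] <- rep(baits,
                                      each = config$n_exclusive_per_bait)
  effect <- rep(NA_real_, length(prots))
  effect[role == "interactor"] <- stats::runif(
    length(int), config$log2_effect_range[1], config$log2_effect_range[2])

  base <- stats::rnorm(length(prots), mu, sig)
  base[role == "contaminant"] <- stats::rnorm(length(con), mu + 3, sig / 2)
  base[role == "bait"] <- stats::rnorm(length(baits), mu + 3, sig / 2)

  truth <- data.frame(protein_acc = prots, role = role, bait_id = cognate,
                      true_log2_effect = effect, stringsAsFactors = FALSE)
  lengths <- stats::setNames(sample(100:1500, length(prots), replace = TRUE),
                             prots)

  nS <- nrow(sheet)
  # expected log2 intensity per (protein, sample); NA = structurally absent
  gen <- matrix(rep(base, nS), length(prots), nS,
                dimnames = list(prots, sheet$sample_id))
  for (i in seq_along(prots)) {
    if (role[i] %in% c("bait", "exclusive"))
      gen[i, sheet$bait_id != cognate[i]] <- NA
    if (role[i] == "interactor")
      gen[i, sheet$bait_id == cognate[i]] <-
        gen[i, sheet$bait_id == cognate[i]] + effect[i]
  }
  lnval <- gen + matrix(stats::rnorm(length(gen), 0, sdn),
                        nrow(gen), ncol(gen))
  pdet <- stats::plogis((lnval - config$detection_midpoint) /
                        config$detection_scale)
  det <- !is.na(lnval) &
    matrix(stats::runif(length(gen)), nrow(gen)) < pdet
  intensity <- ifelse(det, 2^lnval, NA_real_)
  scount <- matrix(0L, nrow(gen), ncol(gen), dimnames = dimnames(gen))
  scount[det] <- 1L + stats::rpois(sum(det),
                                   pmin(intensity[det] / kappa, 1e4))

  # peptide repertoire; preys are guaranteed >= 2 sequences with
  # probability prey_two_peptide_prob so criterion "≥2 unique peptides"
  # is attainable for them
  n_pep <- pmax(1L, stats::rpois(length(prots), 1 + lengths / 400))
  prey <- role %in% c("interactor", "exclusive")
  force2 <- prey & n_pep < 2 &
    stats::runif(length(prots)) < config$prey_two_peptide_prob
  n_pep[force2] <- 2L
  pep_seqs <- lapply(n_pep, .rand_peptide)
  pep_w <- lapply(n_pep, function(k) {
    w <- stats::rgamma(k, 1); w / sum(w)
  })

  nrow_tab <- sum(n_pep)
  tab <- data.frame(protein = rep(prots, n_pep),
                    peptide = unlist(pep_seqs), stringsAsFactors = FALSE)
  ofs <- c(0L, cumsum(n_pep))
  for (j in seq_len(nS)) {
    iv <- numeric(nrow_tab); cv <- integer(nrow_tab)
    for (i in which(det[, j])) {
      k <- n_pep[i]
      idx <- (ofs[i] + 1L):ofs[i + 1L]
      cnt <- as.integer(stats::rmultinom(1, scount[i, j], pep_w[[i]]))
      iv[idx] <- intensity[i, j] * cnt / scount[i, j]
      cv[idx] <- cnt
    }
    tab[[paste0(sheet$sample_id[j], ".intensity")]] <- iv
    tab[[paste0(sheet$sample_id[j], ".sc")]] <- cv
  }

  qm <- .aggregate_quant(tab, sheet)
  list(quant = qm, peptides = tab, sample_sheet = sheet,
       lengths = lengths, contaminants = con, truth = truth,
       config = config)
}

#' Write a simulated experiment to disk in the package's input dialects
#'
#' Emits `quant_table.tsv`, `samples.tsv`, `proteins.fasta` (random
#' sequences of the simulated lengths), `contaminants.txt` and
#' `truth.tsv`, so the pipeline can be exercised end to end through its
#' public file interface.
#'
#' @param sim a [simulate_apms()] result.
#' @param dir output directory, created if needed.
#' @return invisibly, the named vector of paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(quant = file.path(dir, "quant_table.tsv"),
         samples = file.path(dir, "samples.tsv"),
         fasta = file.path(dir, "proteins.fasta"),
         contaminants = file.path(dir, "contaminants.txt"),
         truth = file.path(dir, "truth.tsv"))
  utils::write.table(sim$peptides, p["quant"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$sample_sheet, p["samples"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(sim$config$seed + 1L)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  seqs <- vapply(sim$lengths, function(L)
    paste(sample(aa, L, replace = TRUE), collapse = ""), "")
  writeLines(paste0(">", names(sim$lengths), "\n", seqs), p["fasta"])
  writeLines(c("# simulated common contaminants", sim$contaminants),
             p["contaminants"])
  utils::write.table(sim$truth, p["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(p)
}

#' Score called interactions against simulation ground truth
#'
#' Sensitivity is the fraction of true spiked (bait, interactor) pairs
#' recovered among the passing calls; the false-discovery rate is the
#' fraction of passing calls that are neither a true interactor pair
#' nor a true exclusive pair. Exclusive preys are scored separately
#' against the SINQ rescue path, and a per-effect-size recovery curve
#' is returned.
#'
#' @param calls merged HCIP record data frame.
#' @param truth the `truth` element of [simulate_apms()].
#' @param min_effect restrict sensitivity to spiked pairs with true
#'   log2 effect at least this; default 0 (all pairs).
#' @return list: `sensitivity`, `fdr` (`NA` when nothing was called),
#'   `exclusive_sensitivity`, `n_true`, `n_called`, `recovery_curve`
#'   (data frame with effect bins).
#' @export
truth_report <- function(calls, truth, min_effect = 0) {
  passed <- calls[calls$passed_filters, , drop = FALSE]
  called <- paste(passed$bait_id, passed$protein_acc, sep = "\r")
  ti <- truth[truth$role == "interactor", , drop = FALSE]
  te <- truth[truth$role == "exclusive", , drop = FALSE]
  true_int <- paste(ti$bait_id, ti$protein_acc, sep = "\r")
  true_exc <- paste(te$bait_id, te$protein_acc, sep = "\r")

  sel <- ti$true_log2_effect >= min_effect
  sens <- if (any(sel)) mean(true_int[sel] %in% called) else NA_real_
  fdr <- if (nrow(passed))
    mean(!(called %in% c(true_int, true_exc))) else NA_real_
  exc_calls <- paste(passed$bait_id[passed$provenance == "sinq_exclusive"],
                     passed$protein_acc[passed$provenance == "sinq_exclusive"],
                     sep = "\r")
  exc_sens <- if (length(true_exc))
    mean(true_exc %in% exc_calls) else NA_real_

  brk <- c(-Inf, 2, 3, 4, 5, Inf)
  bin <- cut(ti$true_log2_effect, brk)
  curve <- data.frame(effect_bin = levels(bin),
                      n = as.integer(table(bin)),
                      recovered = as.integer(
                        tapply(true_int %in% called, bin, sum,
                               default = 0L)),
                      stringsAsFactors = FALSE)
  curve$recovery <- ifelse(curve$n > 0, curve$recovered / curve$n,
                           NA_real_)
  list(sensitivity = sens, fdr = fdr,
       exclusive_sensitivity = exc_sens,
       n_true = sum(sel), n_called = nrow(passed),
       recovery_curve = curve)
}
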