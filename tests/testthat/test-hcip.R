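# Build a QuantMatrix + BscgResult pair by hand so each HCIP criterion
# can be exercised at its boundary.
hcip_fixture <- function() {
  prots <- c("P1", "P2", "P3", "P4", "KRT1", "B1")
  lg <- matrix(rep(18, 6 * 6), 6, 6,
               dimnames = list(prots, sprintf("S%d", 1:6)))
  qm <- make_qm(lg, baits = rep(c("B1", "B2", "B3"), each = 2))
  up <- matrix(3L, 6, 3, dimnames = list(prots, c("B1", "B2", "B3")))
  up["P3", "B1"] <- 1L
  qm$unique_peptides <- up
  bscg <- data.frame(
    bait_id = "B1",
    protein_acc = prots,
    log2fc = c(2, -0.5, 1.5, 0.1, 3, 4),
    p_value = c(0.01, 0.001, 0.04, 0.049, 1e-6, 1e-8),
    q_value = NA_real_,
    n_bait_obs = 2L, n_ctrl_obs = 4L,
    stringsAsFactors = FALSE)
  list(qm = qm, bscg = bscg)
}

test_that("the four-criterion filter admits exactly the qualifying records", {
  fx <- hcip_fixture()
  calls <- call_hcips(fx$bscg, fx$qm, contaminants = "KRT1")
  passed <- calls$protein_acc[calls$passed_filters]
  # P1 passes all; P2 fails positive-fold-change; P3 fails unique
  # peptides; P4 passes (p 0.049 < 0.05, lfc 0.1 > 0); KRT1 is a
  # contaminant; B1 is the bait itself
  expect_setequal(passed, c("P1", "P4"))
  expect_true(all(calls$provenance == "bscg"))
})

test_that("filters are monotone in their thresholds", {
  fx <- hcip_fixture()
  base <- call_hcips(fx$bscg, fx$qm, contaminants = "KRT1")
  stricter_alpha <- call_hcips(fx$bscg, fx$qm, contaminants = "KRT1",
                               alpha = 0.02)
  more_peptides <- call_hcips(fx$bscg, fx$qm, contaminants = "KRT1",
                              min_unique_peptides = 4L)
  key <- function(x) paste(x$bait_id, x$protein_acc)[x$passed_filters]
  expect_true(all(key(stricter_alpha) %in% key(base)))
  expect_true(all(key(more_peptides) %in% key(base)))
})

test_that("merge is a keyed union with comparative precedence, idempotent", {
  fx <- hcip_fixture()
  calls <- call_hcips(fx$bscg, fx$qm, contaminants = "KRT1")
  ex <- data.frame(bait_id = c("B2", "B3"),
                   protein_acc = c("X1", "X2"),
                   max_sinq = c(2e-6, 5e-7),
                   total_spectral_count = c(4L, 6L),
                   stringsAsFactors = FALSE)
  merged <- merge_hcips(calls, ex)
  expect_identical(nrow(merged), nrow(calls) + 2L)
  expect_setequal(merged$provenance[merged$protein_acc %in% c("X1", "X2")],
                  "sinq_exclusive")
  expect_true(all(merged$passed_filters[merged$provenance ==
                                          "sinq_exclusive"]))
  expect_true(all(is.na(merged$p_value[merged$provenance ==
                                         "sinq_exclusive"])))
  # idempotence
  expect_identical(merge_hcips(merged, ex), merged)

  # a pair scored by the comparative route keeps provenance bscg
  ex2 <- data.frame(bait_id = "B1", protein_acc = "P1", max_sinq = 1e-6,
                    total_spectral_count = 8L, stringsAsFactors = FALSE)
  merged2 <- merge_hcips(calls, ex2)
  expect_identical(nrow(merged2), nrow(calls))
  expect_identical(
    merged2$provenance[merged2$protein_acc == "P1"], "bscg")

  # an unscoreable comparative record (p NA, no controls) is upgraded
  calls3 <- calls
  calls3 <- rbind(calls3, within(calls3[1, ], {
    protein_acc <- "EXCL1"; p_value <- NA_real_; log2fc <- NA_real_
    q_value <- NA_real_; n_ctrl_obs <- 0L; passed_filters <- FALSE
  }))
  ex3 <- data.frame(bait_id = "B1", protein_acc = "EXCL1",
                    max_sinq = 3e-6, total_spectral_count = 5L,
                    stringsAsFactors = FALSE)
  merged3 <- merge_hcips(calls3, ex3)
  r <- merged3[merged3$protein_acc == "EXCL1", ]
  expect_identical(r$provenance, "sinq_exclusive")
  expect_true(r$passed_filters)
  expect_identical(nrow(merged3), nrow(calls3))
})

test_that("merged size follows set arithmetic on a synthetic run", {
  sim <- simulate_apms(simulation_config(n_baits = 6, n_background = 80,
                                         n_interactors_per_bait = 3,
                                         n_exclusive_per_bait = 2,
                                         n_contaminants = 5, seed = 21))
  bg <- define_background(sim$quant, sim$contaminants, 0.9)
  nm <- normalize_to_background(sim$quant, bg)
  bscg <- score_all_baits(nm, seed = 21)
  tb <- sinq_table(sim$quant, sim$lengths)
  ex <- find_exclusives(tb, sim$quant$samples, sim$contaminants)
  calls <- call_hcips(bscg, sim$quant, sim$contaminants, sinq = tb)
  merged <- merge_hcips(calls, ex, sim$quant)
  already <- paste(calls$bait_id, calls$protein_acc)
  expect_identical(nrow(merged),
                   nrow(calls) +
                     sum(!paste(ex$bait_id, ex$protein_acc) %in% already))
  expect_identical(sum(merged$passed_filters),
                   sum(calls$passed_filters) + nrow(ex))
})

test_that("network degrees, counts and sharing histogram are consistent", {
  h <- rbind(hcip_row("B1", "P1"), hcip_row("B1", "P2"),
             hcip_row("B2", "P1"), hcip_row("B2", "P3"),
             hcip_row("B3", "P1", provenance = "sinq_exclusive",
                      p = NA, lfc = NA, sinq = 1e-6),
             hcip_row("B3", "P4", passed = FALSE))
  lg <- matrix(18, 4, 6, dimnames = list(c("P1", "P2", "P3", "B1"),
                                         sprintf("S%d", 1:6)))
  qm <- make_qm(lg, baits = rep(c("B1", "B2", "B3"), each = 2))
  net <- build_network(h, qm)
  expect_identical(nrow(net$edges), 5L)
  expect_equal(unname(net$bait_counts), c(2L, 2L, 1L))
  expect_identical(unname(net$prey_degree[c("P1", "P2", "P3")]),
                   c(3L, 1L, 1L))
  # sum of per-bait counts equals the edge count
  expect_identical(sum(net$bait_counts), nrow(net$edges))
  hist <- sharing_distribution(net)
  expect_equal(unname(hist), c(2L, 0L, 1L, 0L))
  # sum of histogram equals number of distinct preys
  expect_identical(sum(hist), length(net$prey_degree))
  # degree >= 4 lands in the top bin
  h5 <- do.call(rbind, lapply(sprintf("B%d", 1:5), hcip_row, prot = "PX"))
  lg5 <- matrix(18, 1, 10, dimnames = list("PX", sprintf("S%d", 1:10)))
  qm5 <- make_qm(lg5, baits = rep(sprintf("B%d", 1:5), each = 2))
  expect_equal(unname(sharing_distribution(build_network(h5, qm5))),
               c(0L, 0L, 0L, 1L))
  # raw abundance picks up the bait's own self-pull-down rows
  expect_equal(unname(net$raw_abundance["B1"]), sum(2^18 * c(1, 1)))
})

test_that("abundance correlation matches the closed-form oracle", {
  net <- structure(list(
    edges = data.frame(), prey_degree = integer(0),
    bait_counts = c(B1 = 2L, B2 = 5L, B3 = 9L, B4 = 1L, B5 = 7L),
    raw_abundance = c(B1 = 1e6, B2 = 4e6, B3 = 6e6, B4 = 9e5, B5 = 5.5e6)),
    class = "InteractionNetwork")
  out <- abundance_hcip_correlation(net)
  expect_equal(out$r, oracle_pearson(net$raw_abundance,
                                     as.numeric(net$bait_counts)),
               tolerance = 1e-12)
  # exact proportionality gives r = 1
  net$raw_abundance <- net$bait_counts * 1e5
  expect_equal(abundance_hcip_correlation(net)$r, 1)
  # constant counts: undefined, reported missing with a warning
  net$bait_counts[] <- 3L
  expect_warning(out0 <- abundance_hcip_correlation(net), "variance")
  expect_true(is.na(out0$r))
})

test_that("secretory classification is any-of over the four flags", {
  ann <- data.frame(
    protein_acc = sprintf("P%d", 1:10), length_aa = 300L,
    has_tmd = c(TRUE, rep(FALSE, 9)),
    has_signal_peptide = c(FALSE, TRUE, rep(FALSE, 8)),
    has_nglyc = c(FALSE, FALSE, TRUE, rep(FALSE, 7)),
    has_disulphide = c(rep(FALSE, 3), TRUE, rep(FALSE, 6)),
    stringsAsFactors = FALSE)
  h <- do.call(rbind, lapply(sprintf("P%d", 1:11), function(p)
    hcip_row("B1", p)))
  cls <- classify_secretory(h, ann)
  expect_identical(cls$classes$class[cls$classes$protein_acc == "P1"],
                   "ER/membrane")
  expect_identical(cls$classes$class[cls$classes$protein_acc == "P5"],
                   "soluble")
  expect_identical(cls$classes$class[cls$classes$protein_acc == "P11"],
                   "unknown")
  # 4 of 10 annotated preys carry a flag; the unannotated one is excluded
  expect_equal(cls$fraction_er, 4 / 10)
})

test_that("prior-knowledge overlap is unordered-pair set intersection", {
  h <- do.call(rbind, lapply(sprintf("P%02d", 1:20), function(p)
    hcip_row("B1", p)))
  prior <- data.frame(protein_a = c("P03", "B1", "Z1"),
                      protein_b = c("B1", "P17", "Z2"),
                      stringsAsFactors = FALSE)
  ov <- known_overlap(h, prior)
  expect_identical(ov$n_known, 2L)
  expect_identical(ov$n_total, 20L)
  expect_equal(ov$fraction, 0.1)
  expect_setequal(ov$edges$protein_acc[ov$edges$known], c("P03", "P17"))
  # empty prior list: nothing known; full coverage: fraction 1
  expect_identical(known_overlap(h, prior[0, ])$n_known, 0L)
  all_prior <- data.frame(protein_a = "B1",
                          protein_b = sprintf("P%02d", 1:20))
  expect_equal(known_overlap(h, all_prior)$fraction, 1)
})

test_that("heat-map clustering places identical profiles adjacently and separates blocks", {
  mk <- function(bait, preys, p = 1e-6)
    do.call(rbind, lapply(preys, function(pr) hcip_row(bait, pr, p = p)))
  h <- rbind(mk("A1", c("P1", "P2", "P3")), mk("A2", c("P1", "P2", "P3")),
             mk("B1", c("Q1", "Q2")), mk("B2", c("Q1", "Q2")))
  out <- cluster_pvalue_heatmap(h)
  pos <- setNames(seq_along(out$bait_order), out$bait_order)
  expect_equal(abs(pos["A1"] - pos["A2"]), 1, ignore_attr = TRUE)
  expect_equal(abs(pos["B1"] - pos["B2"]), 1, ignore_attr = TRUE)
  # block structure separates the two bait groups on the prey axis too
  ppos <- setNames(seq_along(out$prey_order), out$prey_order)
  expect_true(max(ppos[c("Q1", "Q2")]) < min(ppos[c("P1", "P2", "P3")]) ||
                min(ppos[c("Q1", "Q2")]) > max(ppos[c("P1", "P2", "P3")]))
  expect_equal(dim(out$matrix), c(4L, 5L))
  expect_equal(sort(unique(as.vector(out$matrix))), c(0, 6))

  # single prey: trivial ordering with a warning
  expect_warning(single <- cluster_pvalue_heatmap(mk("A1", "P1")),
                 "input order")
  expect_identical(single$prey_order, "P1")
})
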