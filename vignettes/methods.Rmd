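---
title: "Scoring multi-bait AP-MS panels with bait-specific control groups"
author: "apmscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring multi-bait AP-MS panels with bait-specific control groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The design this package scores

`apmscore` analyses parallel AP-MS screens in which a panel of tagged
baits (the motivating case: ER-membrane E3 ubiquitin ligases,
21 baits, each injected twice to give technical duplicates) is
purified under one protocol and quantified label-free at the
peptide/protein-group level. There is no mock-IP control; instead each
bait's samples are compared against the pooled samples of all other
baits — the *bait-specific control group* (BSCG). The assumption doing
the work is that a genuine interactor of bait *b* is enriched in *b*'s
pull-downs relative to the other pull-downs, while resin binders,
chaperones and other promiscuous proteins co-purify everywhere and
cancel out. The design fails, by construction, for an interactor
shared by most of the panel: it looks like background. That is a known
property, not a bug, and it is why shared-machinery preys (e.g. an
AAA-ATPase extracted by many ligases) are better examined by their
per-bait spectral-count profiles (`spectral_count_profile()`) than by
fold changes.

## Normalization

The *background proteome* is the set of proteins detected in at least
a fraction `background_threshold` (default 0.9) of all samples, minus
contaminants. The default deliberately stops short of requiring
presence in literally every run: a single failed injection should not
empty the background. Fewer than 10 members is treated as an error —
median-of-ratios scaling over a handful of proteins is not reliable.

Scaling is median-of-ratios against that background. Each background
protein gets a row reference — the *geometric mean* of its observed
intensities — and each sample's scale factor is the median over
background members of intensity/reference. The geometric-mean
reference (rather than a row median) is chosen for an invariance
argument: if one sample's raw intensities are rescaled by any *c* > 0
(a different injection amount, say), every row reference moves by
*c*^(1/n), the common factor cancels in the ratios, and all downstream
log2 fold changes and test statistics are unchanged. With a median
reference the rescaling moves different rows' medians by different
amounts and results drift. Median ties resolve to the midpoint of the
two central order statistics.

## Enrichment statistics

Intensities get a pseudocount of 1 intensity unit before log2 — enough
to keep near-zero cells finite, negligible against real MS1 summed
intensities (~10^5–10^8).

**Missing data.** A cell is missing exactly when no spectrum was
assigned (spectral count 0). Missing *bait* cells are dropped:
detection in the bait with absence elsewhere is the signal of
interest and must not be erased. Missing *control* cells are handled
adaptively:

* observed in ≥ half of the controls → missing cells are dropped.
  Sporadic dropout of a well-observed protein carries little
  information, and imputing detection-limit values into an otherwise
  complete group grossly inflates its variance estimate (we measured
  the null p < 0.05 rate falling to ~0.03 under unconditional
  imputation);
* observed in < half of the controls → missing cells are imputed from
  the sample's low-abundance region, N(1st percentile of the sample's
  observed log2 intensities, sd = median within-protein sd), because
  widespread absence from the control group *is* evidence of low
  abundance there. Draws are seeded and made once per (protein,
  sample) cell, shared across all baits, so results are deterministic
  and equivariant under bait relabelling;
* observed in no control → no fold change can be formed. The record
  carries `p_value = NA`, `n_ctrl_obs = 0`, and is the input to the
  SINQ exclusivity rescue.

**The test.** The default statistic is a pooled-variance two-sample t
with empirical-Bayes variance shrinkage across proteins
(`limma::squeezeVar()`). The reason is the replicate structure: with
n = 2 technical duplicates per bait, the per-protein bait variance has
one degree of freedom, and the Welch t-test is badly anticonservative
there (measured size ~0.12 at nominal 0.05 for n = 2 vs 40 normal
samples), because a lucky tiny s² both shrinks the denominator and
inflates the Satterthwaite degrees of freedom. Variance moderation
borrows the panel-wide degrees of freedom and restores the size to
~0.05. The plain Welch test remains available (`test = "welch"`) and
is the strategy checked against closed-form and permutation oracles in
the test suite. Degenerate inputs are defined: both groups constant
and equal gives p = 1; constant, unequal gives p = 0.

No multiple-testing correction is applied to the reported p-values —
the HCIP criterion is raw p < 0.05 — but Benjamini–Hochberg q-values
(within bait) are reported as a column for users who want them.

## SINQ and the exclusivity rescue

Per sample, a detected protein's spectral index is its summed peptide
intensity; the SINQ score divides by the sample total and by the
protein length in residues, so that Σ score × length = 1 within each
sample. The index source is MS1 peptide intensity by default;
`use_counts = TRUE` substitutes spectral counts when intensities are
unavailable. The score is invariant to rescaling a sample's
intensities.

A protein detected with exactly one bait and absent from every other
bait's samples is called an exclusive interactor when (1) its best
per-sample SINQ score is ≥ `min_sinq` = 1×10⁻⁷, (2) its spectral
counts summed over the bait's samples are > `min_sc` = 1 (summing
across technical duplicates is the permissive reading; the scope is
configurable), and (3) it is not a contaminant. A bait never rescues
its own accession. At merge time, comparative records that could not
be scored (`p_value` missing) are upgraded in place by a matching
exclusive call; records with a p-value always take precedence, so a
pair seen by both routes stays `bscg`.

## The HCIP filter and network summaries

A record passes when p < `alpha` (0.05), log2FC strictly > 0 (a tie at
exactly 0 fails), unique peptides ≥ 2 within the bait's samples, and
the prey is not a contaminant. The bait's own accession is excluded
from the edge list; its self-pull-down intensity is retained as the
bait's raw abundance for the abundance-vs-HCIP-count correlation.
Preys absent from the annotation table are classed `unknown`, never
silently `soluble`. Heat-map clustering uses average linkage on
Euclidean distances over −log10 p (missing → 0); linkage and metric
are arguments because nothing in the method fixes them.

## What the simulator emulates — and what it does not

`simulate_apms()` generates: per-protein base log2 intensities
N(μ = 20, σ = 2) (a typical Progenesis-scale summed-intensity
distribution); bait-specific enrichment effects Uniform(2, 6) log2
added in cognate samples; exclusives generated only in cognate
samples; 30 contaminants present everywhere at high abundance; cell
noise N(0, log2(1 + 0.25)); logistic intensity-dependent detection
(midpoint 13, scale 1.5 — the background proteome is ~97–99% complete,
with enough dropout to exercise the missing-data policy); spectral
counts 1 + Poisson(I/κ) with κ = 2^(μ−1), putting the background
median spectral count near 3 so the > 1-count criterion bites; protein
lengths Uniform{100..1500}; and a peptide repertoire whose per-sample
detection makes unique-peptide counts rise with abundance (spiked
preys are guaranteed ≥ 2 sequences with probability 0.95). Everything
is a deterministic function of the seed.

It does **not** emulate: retention-time alignment artefacts, shared
peptides and protein-group ambiguity, batch effects or bait-level
random effects (samples are exchangeable within the generative model),
interactors shared across baits, or correlated contaminant behaviour.
Consequently, passing recovery tests on simulated data demonstrates
the statistical machinery under the stated model; it does not certify
performance on real panels, where between-run correlation typically
makes the control group overdispersed and the raw-p filter less
permissive than the nominal level suggests.

Default problem sizes (21 baits × 2 duplicates, 400 background
proteins, 8 interactors + 2 exclusives per bait) are chosen so a full
pipeline run completes in a couple of seconds while recovery
statistics are stable across seeds.

## Known limitations

* **The raw p < 0.05 criterion has no error-rate guarantee.** With
  ~12,500 scored records and a calibrated test, about 2.5% of null
  records show p < 0.05 with positive fold change; on the default
  simulation that is more chance positives than true spiked pairs,
  and the empirical FDR of the passing set sits near 0.4 (the
  acceptance script computes it each run). This is a property of the
  filter definition, not of the implementation: any calibrated test
  behaves this way. The reported q-value column is the principled
  alternative for users who need FDR control.
* **Low-abundance exclusives below the SINQ cutoff are lost.** The
  1×10⁻⁷ score threshold is absolute; long, low-intensity
  bait-exclusive preys fall under it and are correctly (per the
  filter) but irrecoverably rejected — on default simulations this
  costs roughly 15% of true exclusives.
* Panel-wide interactors are invisible to the BSCG contrast (above).
* Protein-group inference, match-between-runs and PSM-level FDR are
  upstream of this package's inputs and out of scope.

## End-to-end example

```{r pipeline}
library(apmscore)
sim <- simulate_apms(simulation_config(seed = 1))
paths <- write_simulation(sim, "demo")
cfg <- pipeline_config(paths["quant"], paths["samples"], paths["fasta"],
                       paths["contaminants"], seed = 1,
                       out_dir = "demo/out")
res <- run_pipeline(cfg)
truth_report(res$hcips, sim$truth, min_effect = 2)
```
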