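---
title: "Methods: from co-expression networks to activity QTLs"
author: "aqtlkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from co-expression networks to activity QTLs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Expression QTL (eQTL) mapping asks whether a genetic variant shifts a
gene's transcript level. But a variant can change what a regulatory
protein *does* — its efficacy on downstream targets — without changing how
much of its transcript is present: a coding change, a modification site, a
protein-interaction change. Such effects are invisible to eQTL analysis
yet fully visible in the behavior of the regulator's target genes.
`aqtlkit` implements an *activity-QTL* (aQTL) workflow: regulator
activities are inferred from the coordinated behavior of their targets in
a co-expression network, and those activities are then treated as a
molecular trait and mapped against GWAS variants exactly as transcripts
are. The package also selects *master regulators* (MRs) — regulators whose
activities best predict a phenotype — and colocalizes QTL signals with
GWAS signals.

Because the cohorts this kind of analysis is run on are controlled-access,
the package ships a synthetic-data generator with planted effects; every
stage is therefore testable end to end with known ground truth.

# Stage 1: co-expression network inference

The network is inferred from mutual information (MI) between each
regulator (from a user-supplied list of transcription factors, co-factors
and signalling genes) and every other expressed gene, in three steps:

1. **MI significance threshold.** Null MI values are computed for randomly
   chosen gene pairs after permuting one member's sample labels. An
   exponential tail, `ln P(MI > t) = a + b t`, is fit to the upper 5% of
   the null and extrapolated to the target tail probability (default
   1e-8 — far beyond what raw permutation can reach).
2. **Bootstrap networks.** Samples are resampled with replacement; in each
   bootstrap, MI is computed for all regulator–gene pairs, pairs below the
   threshold are dropped, and the data-processing inequality (DPI) removes
   the weakest edge of every triangle (an indirect dependence).
3. **Consensus.** An edge is kept when its bootstrap support count is
   significant under a Poisson null whose rate spreads the total number of
   edge occurrences uniformly over all candidate pairs, Bonferroni-corrected
   at 0.05 across candidates.

MI is estimated in nats by recursive adaptive partitioning of the
rank-transformed plane: a cell splits into quadrants at the midpoints of
its rank ranges while a chi-square statistic over the four quadrant counts
exceeds a critical value (default 7.815, the nominal df = 3, alpha = 0.05
point), and terminal cells contribute
`(n_c/N) ln(n_c N / (n_x n_y))`. Two numerical properties matter in
practice:

* Because quadrant counts are constrained by the rank marginals, the root
  split fires for roughly 0.5% of independent pairs, not the nominal 5% —
  the estimator is conservative, and the null distribution has most of its
  mass at exactly zero. The threshold estimator therefore fits its tail on
  the *positive* null values and draws additional permutation batches (up
  to ten) until at least 50 positive values exist.
* Rank-based MI is exactly invariant under strictly increasing transforms
  of either variable. An order reversal reflects the rank plane, which can
  shift the integer midpoint partition by one rank and perturb the
  estimate by about a percent — immaterial, but worth knowing when writing
  exact equality tests.

Defaults are sized for a workstation: 50 bootstraps and 10,000 null pairs
per batch (the `paper` profile of `pipeline_config()` records the
published-scale settings of 900 bootstraps). DPI tie-breaks remove the
lexicographically last pair id, making pruning deterministic.

# Stage 2: regulons and activity scores

The network is converted into an interactome: per edge, the *mode of
regulation* `m` is the signed Spearman correlation between regulator and
target expression (in [-1, 1]), and the *likelihood* `w` is the edge MI
scaled by the regulon's maximum MI (so each regulon's top target has
`w = 1`).

For scoring, expression is z-scaled per gene, then each sample's gene
values are rank-transformed within the sample to quantiles
`(rank - 0.5)/G` and mapped through the standard-normal quantile function
to scores `u`. The activity of regulator `r` in sample `s` is the
normalized enrichment score

$$ \mathrm{NES}_r(s) \;=\; \frac{\sum_i w_i\, m_i\, u_i(s)}{\sqrt{\sum_i w_i^2}} . $$

With unit-magnitude modes this is exactly standard normal when targets
behave independently, which makes the null testable: on random expression
the per-regulator NES mean lies in (−0.05, 0.05) and the sd in (0.9, 1.1)
for regulon sizes 25–200 over 1000 samples. This is a deliberately
simplified single-component weighted-enrichment score: multi-tail blends
used by some activity-inference tools lack a closed-form null, and the
calibration property was judged worth the simplification. Activities are
only inferred for regulators with at least 25 expressed targets ("expressed"
meaning present in the matrix at scoring time, after any low-expression
filtering).

**Pleiotropy correction.** When two regulons share at least `min_common`
targets (default 25) and one has the stronger score on a sample, the
weaker regulator's score is recomputed on its unique targets and blended
with the original as `alpha * original + (1 - alpha) * unique` (default
`alpha = 0.5`). This is an explicit, deterministic rule standing in for
shadow-style corrections whose internals vary between tools; it can be
disabled, and `alpha = 1` is the identity.

# Stage 3: master regulators

MRs for a phenotype are selected with random-forest regression
(`randomForest`, 500 trees, `mtry = p/3` — the regression convention) in
three steps: a cross-validated error curve over predictor counts reduced
sequentially by five (12 repeats, each with its own seed; 5-fold CV); a
parsimonious predictor count chosen by the one-standard-error rule (the
smallest count whose mean CV error is within one sd of the minimum — an
explicit, testable replacement for choosing "by inspection", with the
curve returned so users can override); and a final forest on the top-K
regulators by permutation importance, trained on a 70:30 split and
evaluated by Pearson correlation on the held-out 30%. Importance is
reported as the percent increase in out-of-bag MSE upon permutation,
computed from the forest's raw permutation importance divided by the OOB
MSE. Missing phenotypes drop samples; the response is never imputed. A
generic phenotype-stability filter (keep samples whose value changed less
than 10% between two measurement columns) supports phenotypes measured at
a different time than the molecular data.

# Stage 4: cis/trans eQTL and aQTL mapping

QTL scans are restricted to GWAS-significant variants. *Cis* pairs are
variant–regulator pairs within 1 Mb of the TSS (1-based, boundary
inclusive); *trans* pairs cross every selected variant with the
phenotype's MR set, excluding pairs meeting the cis criterion. Each
association is an OLS fit of the trait (z-scaled expression for eQTLs,
NES for aQTLs — activities are already near-standard-normal and are used
as-is) on dosage with age and the top 5 genotype principal components as
covariates; the scan residualizes trait and dosages against the
covariates once, which by Frisch–Waugh reproduces the full OLS t-test
exactly.

Multiple testing follows a gene-wise minimum-P procedure: for gene *k*
with *n* tested variants, the observed statistic is the minimum
association p-value; its null distribution is obtained by jointly
permuting the sample indices of the gene's genotype block (2,000
permutations at desk scale, 100,000 in the `paper` profile). Joint
permutation preserves the LD among the variants exactly while severing
the genotype–trait link. The gene-wise p-value is

$$ q_k = \frac{1 + \#\{\text{sims with min-p} \le P_k\}}{1 + n_\text{sim}}, $$

never zero by construction. Under permutation the statistic is the
covariate-residualized correlation without re-projecting the permuted
block — the standard QTL-permutation shortcut; the uniformity of `q_k` on
null data is verified by test. Benjamini–Hochberg is applied across genes
at FDR 0.05 (`stats::p.adjust`), and the nominal trans-significance
threshold is recovered by inverting the empirical null CDF at the largest
gene-wise p among BH-passing genes. The cis-versus-trans comparison of
aQTL and eQTL strength uses the pooled two-proportion z-test on the
indicator `p_aQTL < p_eQTL` (strict inequality).

# Stage 5: colocalization

Pairwise colocalization uses Wakefield approximate Bayes factors per
variant,

$$ \log \mathrm{ABF} = \tfrac12 \log\!\frac{se^2}{se^2 + W^2} +
   \frac{z^2}{2}\,\frac{W^2}{se^2 + W^2}, $$

with effect-prior sd `W = 0.15`, and enumerates the five hypotheses (no
signal; one trait only; two distinct variants; one shared variant) with
per-variant priors `p1 = p2 = 1e-4`, `p12 = 1e-5`. The posterior of a
shared variant is classified as *none* (PP ≤ 0.25), *weak*
(0.25 < PP ≤ 0.50) or *well* (PP > 0.50). This pairwise formulation was
chosen over multi-trait regional algorithms because it has an exactly
enumerable oracle (the linear-space hypothesis sums), so every posterior
the package emits can be verified independently in tests; posteriors from
multi-trait tools with different priors will differ numerically. Dense
locus scans (all variants in a 1 Mb window around a lead variant,
regardless of GWAS significance) feed colocalization only and carry no
multiple-testing correction.

# The synthetic cohort

The generator emulates exactly the structure the analyses assume, as a
linear-Gaussian system with standardized regulator variables:

* genotypes: biallelic dosages, Binomial(2, p) with MAF drawn from
  [0.05, 0.5], in LD blocks of 5 generated by thresholded latent AR(1)
  haplotypes with correlation 0.6;
* regulator transcripts `X = beta_e g + eps` (eQTL channel,
  `beta_e = 0.8` sd);
* activities `A = lambda X + beta_a g' + eps` (`lambda = 0.7`,
  `beta_a = 0.8`): the `beta_a` channel alters efficacy without touching
  the transcript, through a cis variant or a trans-acting variant on a
  separate chromosome;
* targets `X_t = m w A + eps_t` with modes |m| in [0.5, 1] of random sign,
  45–65 exclusive targets per regulator, plus passenger genes;
* phenotype `Y = sum c_r A_r + eps_y` over 5 true MRs at heritability 0.5,
  with an age column independent of Y by default (a config switch adds
  confounding so covariate adjustment is testable both ways);
* GWAS summary statistics by marginal per-variant OLS of Y.

The coupling `lambda = 0.7` deserves a note. With weak transcript–activity
coupling, an activity-only regulator's targets barely covary with its
transcript, and *no* transcript-based network method can learn its regulon
— its aQTLs become undetectable for a structural reason rather than a
power reason. At 0.7 the regulon is learnable while the activity channel
still dominates the transcript channel for planted aQTL regulators, which
is the regime of interest.

What the generator does **not** emulate: realistic allele-frequency
spectra, population structure or relatedness, nonlinear regulation,
count-level measurement noise, sex chromosomes. Passing tests demonstrate
that the machinery is correct and calibrated under the stated linear
model, not that real-data discoveries at published scale are reproduced —
those rest on controlled-access cohorts.

# Numerical choices and problem sizes

* All randomness flows through explicit seeds (Mersenne-Twister; a helper
  restores the caller's RNG state), so every result is exactly
  reproducible; the pipeline manifest records parameters, seeds and output
  file MD5 hashes, and a rerun reproduces identical hashes.
* Rank ties: average ranks inside the per-sample normal scores; first-come
  ranks inside MI (deterministic under bootstrap duplication).
* The low-expression rule keeps a gene when it exceeds the minimum
  per-sample scaling factor in at least 5% of samples (strictly fewer
  excludes); the boundary is computed as `count >= ceiling(0.05 n)` with a
  small numerical guard. The log2 pseudocount default is 1e-3 TPM
  (configurable).
* Dosage input: the VCF `DS` field when present, otherwise the `GT`
  alt-allele count; multi-allelic records are skipped with a message.
* Desk-scale sizes used throughout the test-suite and acceptance runs:
  n = 500 samples, 12 regulators (~700 genes) for the end-to-end pipeline;
  50 bootstraps; 2,000 permutations per gene; 500 null genes for QTL
  calibration; 20–50 replicates for rate estimates. The GWAS selection
  cutoff in the desk pipeline profile is 1e-5, because a marginal GWAS at
  n = 500 cannot routinely reach 5e-8; the QTL-stage default for real
  summary statistics remains 5e-8.

# Known limitations

* The activity score is single-component (signed, two-tail); regulons
  whose targets split into antagonistic programs are summarized by one
  number.
* The pleiotropy rule conditions on per-sample score magnitudes and can
  over-correct a genuinely co-active pair of overlapping regulons.
* The empirical gene-wise null assumes exchangeable samples after
  covariate residualization; kinship or strong structure would need a
  mixed-model extension, which is out of scope.
* Colocalization assumes at most one causal variant per trait per locus;
  allelic heterogeneity inflates the distinct-variant hypothesis.
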