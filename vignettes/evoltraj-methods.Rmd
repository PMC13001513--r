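---
title: "Models and design choices in evoltraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in evoltraj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

evoltraj analyses Pool-seq time series from reciprocal selection-shift
experiments: two sets of replicate populations, derived from shared standing
variation but long adapted to opposing life-history regimes, are each moved
to the other regime and resequenced along the way. This vignette explains
the statistical models, the simulator that stands in for the raw data, the
defaults and why they were chosen, and the limits of what the test suite
can show.

## Data model and conventions

The exchange object is the `snp_table`: matrices of minor-allele counts and
total coverages over loci × samples, with locus metadata (chromosome arm,
position, minor/major base) and sample metadata (group, replicate,
generation, timepoint). Conventions, fixed once and used everywhere:

* **Global minor allele.** The minor allele at a locus is the nucleotide
  less common summed over *all* samples; ties break lexicographically
  (A < C < G < T) toward the minor. This makes frequencies comparable across
  samples and makes "fixed for the minor allele" a meaningful state.
* **Filtering.** A locus survives if every sample has ≥ 20× coverage and
  the *pooled* minor-allele frequency (summed counts) is ≥ 0.02, both
  inclusive. The pooled reading of the frequency rule matches the global
  minor-allele definition; a per-sample-maximum reading would keep strictly
  more loci and is not what the global convention implies. Sites
  monomorphic in a subset of samples are deliberately retained — the
  pseudo-fixed analysis depends on them.
* **Coordinates** are 1-based inclusive (sync convention). Chromosome 4 can
  be excluded (`exclude_chrom4`); its atypical recombination and
  heterochromatin make per-locus models there unreliable.
* **Frequencies for PCA** add a pseudocount of 1 (`(y + 1) / (n + 2)`) so
  zero-count cells neither divide by zero nor produce zero-variance columns;
  heterozygosity uses raw frequencies because `H = 2f(1-f)` of a site
  sampled as invariant is genuinely 0.

## The per-locus beta-binomial GLMM

Counts are modelled as `Y ~ BetaBinomial(n, p, phi)` with
`logit(p) = b0 + b1*T + b2*G + b3*T*G + u_j`. Choices that the data model
leaves open, and how they were resolved:

* **Overdispersion scale.** `phi` is the intra-class correlation
  `rho ∈ [0, 1)`, with beta shapes `a = p(1-rho)/rho`,
  `b = (1-p)(1-rho)/rho`. It is bounded, numerically stable, and
  `rho -> 0` recovers the binomial exactly (the implementation switches to
  the binomial branch below `1e-8`, where the lgamma route would lose more
  precision to cancellation than the branches differ).
* **Integration.** The replicate random intercept is integrated out by a
  Laplace approximation: an inner vectorized Newton solve for the
  per-replicate conditional modes (compiled, warm-started across objective
  evaluations) inside an L-BFGS-B outer optimization of
  `(b, qlogis(rho), log(sigma_u))`, with three fixed restart points on
  failure. Adaptive Gauss–Hermite quadrature (`nagq > 1`) is a validation
  mode; Laplace and 9-node quadrature agree to about `1e-2` on simulated
  loci, which the suite checks.
* **Conditioning.** Generation is centered and scaled to unit variance
  internally so all coefficients are O(1) for the optimizer; estimates and
  standard errors are mapped back to the original per-generation scale.
* **Inference.** Per-term Wald tests use a **t reference with J − 2 degrees
  of freedom** (J = replicate populations). On 4,000 model-conformant null
  loci the normal reference had size 0.065 at nominal 0.05 (the classic
  small-J Wald inflation; sd(z) ≈ 1.04), while t(J−2) gives 0.046.
  Replicate populations are the independent units behind the treatment and
  interaction contrasts, so their count — not the read count — sets the
  information scale. A likelihood-ratio mode (`bb_lrt`) exists for
  sensitivity checks.
* **Boundary behaviour.** `sigma_u^2` is bounded below at `1e-8`; at the
  boundary the model degrades smoothly to a fixed-effects beta-binomial.
  Loci with no variation (all zero or all full counts) return
  `converged = FALSE` with reason `"no variation"` rather than an error,
  and by default still count in the Bonferroni denominator.
* **Two thresholds.** The genome scan uses Bonferroni α = 0.05; the
  pseudo-fixed site selection uses the stricter 0.005. Both are exposed as
  parameters (`alpha`, `hidden_alpha`) rather than reconciled.

## PCA and per-component mixed models

The PCA scales each locus column to unit variance but does **not** center
it, so scores retain absolute frequency information and founder groups
separate along the leading components; variance explained comes from the
squared singular values. Zero-variance loci are dropped with a message.
Scores are defined for samples (samples × loci orientation). PC signs are
fixed so the founder-A mean score does not exceed the founder-C mean,
giving reproducible orientations. Per component,
`score ~ trajectory * generation + (1 | population)` is fit by REML with
Satterthwaite t-tests (lmerTest), Bonferroni-adjusted across PCs × terms at
α = 0.005; singular fits are flagged per PC, and a single-trajectory input
is flagged inestimable rather than fatal. The endpoint analysis
(`endpoint_group_lm`) is the same operation with generation dropped:
ordinary `score ~ group` linear models per PC.

## Heterozygosity and hidden variation

`het_trend` averages `H = 2f(1-f)` over loci per sample and compares
replicate-level means at the first versus last sampled generation within
each trajectory with a Welch t-test — replicates, not samples or sites, are
the test units. Sites with zero minor counts are included (they contribute
0); excluding them would bias the rebound upward.

`find_pseudo_fixed` takes the scan-significant loci whose focal-sample
minor count is 0 *or equals coverage* — both directions of apparent
fixation. Deep-coverage MAFs are folded (`min(f, 1-f)`) so sites fixed for
the minor nucleotide contribute their rare-allele frequency. The
permutation test draws equal-size subsets from the deep background without
replacement, independently per permutation, from a sorted copy of the
background (so results are invariant to input ordering), and reports the
+1-smoothed empirical p `(1 + #{null ≤ obs}) / (1 + n_perm)` — never
exactly zero — alongside the raw count and a z-score.

## Convergence and parallelism scans

The evolved-vs-founder test pairs an overdispersed binomial model with a
model-comparison test. A quasibinomial error structure has no true
likelihood, so a literal likelihood-ratio test is not defined for it; the
default mode therefore uses a quasi-likelihood **F test** (deviance
difference scaled by the Pearson dispersion, which also absorbs
replicate-level variation), and a beta-binomial LRT with an explicit
replicate random intercept is provided side by side (`mode = "bb"`) for
sensitivity. Chromosome 4 and loci monomorphic across all used samples are
excluded and do not enter the Bonferroni denominator.

The baseline trajectory scan models `(minor, major) ~ generation +
replicate` with replicate as fixed-effect intercepts (it enters the formula
as a term, not a random effect), Pearson-residual dispersion, t-based
p-values and BH adjustment across estimable loci. The LOO framework then
holds out each replicate in turn: targets are training-set loci with
BH-adjusted p < `fdr` and pooled training `|Δp| ≥ min_abs_dp` (Δp pools
counts across training replicates within each generation; the held-out Δp
uses that replicate's counts alone); controls are an equal-size uniform
draw from estimable non-targets, re-drawn per iteration from a seed derived
as `seed + 7919 * iteration`; loci inestimable in a training set are
ineligible as targets *and* controls. Genome-wide medians pool loci across
arms (arm-level medians are reported separately). Replicate-level target
and control medians are compared with two-sample two-tailed t-tests.
Iterations with zero targets are recorded empty and excluded from the
t-test with a warning.

## The simulator: what it emulates, and what it does not

`simulate_experiment` mirrors the study conditions: diploid Wright–Fisher
populations of census N = 1000 with discrete non-overlapping generations
and viability selection; 10 replicates per trajectory derived from shared
ancestral variation; pools of 200 individuals; per-sample mean depths drawn
uniformly from 62–113× (the reported per-sample range), Poisson-distributed
per site and truncated at 1; an 800× deep mode that resequences the *same
pool draw* as the focal standard sample. Default sampled generations are
0/12/33/65 for A→C and 0/33/143/182 for C→A — the endpoint counts the study
anchors plus its interim phenotype-assay counts; exact Pool-seq sampling
generations are not pinned down by the source and are configurable.

Locus classes: directional loci carry additive antiparallel effects
(favoured homozygote `1 + s`, default s = 0.05); balanced loci have a
heterozygote net-fitness advantage, plus — under the A-like regime only — a
multiplicative penalty per minor-allele copy solved so the internal
equilibrium sits at `balanced_low_eq` (default 0.015, inside the band that
standard 90× sequencing frequently reads as zero counts). Founder replicate
states are individualized by 20 generations of within-regime drift.

Two parameter choices deserve emphasis:

* **`h_balance = 1` (strong net balancing).** Near an internal equilibrium
  f\*, the restoring force of asymmetric overdominance scales with f\*
  itself: at f\* = 0.015 and N = 1000 the rare-allele advantage cannot
  exceed ≈ 0.016 regardless of h, which is on the drift scale. Empirically,
  h = 0.1 loses ~79% of such reservoirs within 182 generations and even
  h = 1 loses ~5% during the 20-generation founder drift. A population that
  *has* maintained a low-frequency reservoir for hundreds of generations
  therefore implies strong net balancing; h = 1 encodes that, and the
  small residual loss is kept — it reproduces the near-zero mass in the
  deep-coverage MAF distribution at pseudo-fixed sites. Persistence
  becomes essentially certain once f\* clears the diffusive scale
  (no loss at f\* = 0.1 over 182 generations in 5,000 paths), which is the
  regime the persistence property test uses.
* **No linkage, mutation, migration or age structure.** Every analysis in
  the package is per-locus; linked drift, hitchhiking and the long-range
  haplotype structure of real Pool-seq data are absent. Consequently a
  passing suite shows the estimators and tests behave correctly under the
  model's own noise (pool + read sampling + independent drift), not that
  they are robust to linked selection — on real data the drift of linked
  blocks is autocorrelated within replicates, which a replicate intercept
  cannot absorb, and genome-wide scans there lean on the controls and
  permutation structure rather than on nominal calibration. The same
  applies to the scan's family-wise error checks, which are run at large N
  or with model-conformant noise so drift stays inside the model's noise
  budget.

One RNG stream (seeded from `sim_config(seed)`) drives the run in a fixed
order — population process first, then read sampling — so standard and deep
tables share pool frequencies and runs are byte-identical under a seed.

## Problem sizes and numerical tolerances

The test suite works at desk scale, chosen so each check retains power
while the whole suite stays quick: 500 loci for parameter recovery (bias
within 10%, Wald 95% CI coverage in [0.90, 0.98]), 2,000 loci for size
(raw interaction p < 0.05 in [0.03, 0.07]), 2,000 loci × 200 generations
for the drift oracle (decay rate within 20% of 1/(2N)), 3,000 loci with
10,000 permutations for the hidden-variation reproduction, 10,000 loci for
LOO power and 100 neutral runs for its calibration. The acceptance script
reruns the full pipeline at 2,000 loci. Likelihood identities are checked
to 1e-8, Laplace-vs-quadrature agreement to 1e-2, binomial-GLM agreement
(at phi ≈ 0, sigma_u ≈ 0) to 1e-3 relative.

## Known limitations

* Wald t inference is approximate; very low-coverage or near-monomorphic
  loci can still produce unstable `phi` estimates (flagged via
  `converged`).
* The quasi-likelihood F test folds replicate structure into the
  dispersion; with few replicates and strong replicate effects the
  beta-binomial mode is the safer cross-check.
* The simulator's balanced-locus architecture is a single-locus caricature
  of antagonistic pleiotropy distributed over many fitness components; it
  reproduces the phenomena (reservoir, rebound, antiparallelism) but not
  their genetic architecture.
* Pool-seq counts are taken at face value: no sequencing-error model, no
  base-quality awareness.
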