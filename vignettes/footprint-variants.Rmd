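---
title: "Models and methods behind footvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind footvar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(footvar)
```

`footvar` annotates non-coding SNPs by their predicted effect on
transcription factor (TF) binding, combining a position weight matrix
(PWM) sequence model with DNase-seq cut profiles, an allele-specific
hypersensitivity (ASH) test, and motif-wise selection statistics. This
vignette documents the models, the tunable parameters, the synthetic
data the tests rest on, and the numerical decisions a maintainer would
want to know about.

## The footprint mixture model

At each candidate site (a motif match extended by `flank` bases on each
side, default 100), the DNase-seq data are the per-position cut-start
counts on both strands, a vector of length `2 * (width + 2 * flank)`.
The site is modelled as a two-component mixture:

* **Bound**: total reads `R ~ NB(mu1, size1)`; positions
  `x | R ~ Multinomial(R, lambda)`, where `lambda` is the footprint
  profile — elevated shoulders at the motif edges, depletion across the
  protein-protected motif, and strand asymmetry (the 5' shoulder is on
  the forward strand upstream, mirrored on the reverse strand).
* **Unbound**: `R ~ NB(mu0, size0)` with a *uniform* spatial profile.
  Keeping the unbound spatial model uniform is what identifies the
  footprint shape; a learned background could be substituted but would
  compete with `lambda` for the same degrees of freedom.

The mixing prior is logistic in the PWM log-odds score `S` (natural
log against the background base frequencies):
`P(bound) = sigmoid(beta0 + beta1 * S)`. Fitting is by EM:

* E-step: `rho = sigmoid(eta + Delta)` with prior log odds
  `eta = beta0 + beta1 * S` and `Delta` the bound/unbound
  log-likelihood ratio of the cut data.
* M-step: `lambda` from posterior-weighted counts plus a total
  smoothing mass of 0.5 spread uniformly (so positions never visited
  keep a nonzero probability and `Delta` stays finite); NB means in
  closed form and sizes by 1-D likelihood search on the log scale,
  bounded in [1e-3, 1e6]; `beta` by weighted logistic regression
  (IRLS via `glm.fit` on the fractional posteriors).

Initialisation assigns `rho = 0.9` to the top decile of PWM scores and
0.1 elsewhere, with `beta = (logit(0.1), 0)` — the same 10% floor used
by the step-2 rescan. Convergence is declared when the relative change
in the observed-data log-likelihood falls below `1e-6` (cap 200
iterations); the trace is stored and tested for monotonicity to within
`1e-8`. If the component means cross (`mu1 < mu0`), labels are swapped
by flipping `rho`; the monotonicity baseline restarts at such a
relabeling. With constant PWM scores the logistic design is collinear;
the slope is then fixed at 0 with an infinite standard error rather
than propagating `NA`s.

**Activity.** A sample–motif pair is *active* when the Wald statistic
`Z = beta1 / se(beta1)` from the final IRLS weights exceeds 5
(strictly; `Z = 5` is inactive). Under separation the standard error
is undefined and the fit carries a `z_capped` flag. The Wald form is
an approximation of convenience; it behaves correctly in the null and
permutation simulations in the test suite.

**Footprints and recalibration.** A *footprint* is a site with
posterior > 0.99 in an active pair. The same 0.99 cutoff defines the
sites used to recalibrate each active motif's PWM (at least 100 sites,
configurable); the catalog-defining posterior cutoff is not separately
specified anywhere we could anchor it, so the recalibration value is
reused. The recalibrated model rescans the genome down to the score
`S* = (logit(0.10) - beta0)/beta1`, i.e. a 10% prior floor. The prior
deliberately uses the PWM score as its only covariate — conservation
and TSS distance are kept out of the annotation so they remain
available as independent axes for downstream characterisation.

## Effect- and switch-SNPs

Each allele of a SNP inside a match is substituted into the
strand-resolved motif column and rescored; the per-allele prior log
odds are `ell = beta0 + beta1 * S(allele)`. Classification:

* **effect**: `|ell_ref - ell_alt| >= 3`. The threshold is implemented
  on the natural-log-odds scale, where 3 corresponds to a
  `e^3 = 20.09`-fold change in prior odds — the only base for which
  "difference of 3" and ">= 20-fold" coincide.
* **switch**: an effect-SNP with `ell >= 0` for one allele and
  `<= 0` for the other; the boundary 0 counts for both signs.

A SNP inside several motifs keeps the motif with the largest
cut-profile likelihood ratio (the factor most likely bound there);
exact ties break lexicographically by motif id so reruns are
deterministic. The catalog is an 8-column BED-style TSV (0-based
half-open): position, motif, the *signed* difference
`ell_ref - ell_alt`, the two per-allele log odds, and the sample. The
signed convention (reference minus alternate) was chosen over an
absolute value so the direction of the predicted change survives the
round trip; the classification itself only uses the magnitude.
Multi-allelic variant records are decomposed into biallelic rows on
VCF input, and every written file carries a comment line stating its
coordinate convention.

## Genotyping and the ASH test

Per sample, read counts at known SNPs are modelled over latent
genotypes with Hardy–Weinberg priors at the population allele
frequency: `RR: Binom(n, 1 - eps)`, `AA: Binom(n, eps)`,
`RA: BetaBinom(n, 1/2, M)` with concentration `M` (larger `M` = less
overdispersion). `eps` (bounds `[1e-4, 0.1]`) and `M` (bounds
`[1, 1e6]`, searched on the log scale) maximise the marginal
likelihood by coordinate ascent; when the likelihood is flat out to
the upper bound of `M` (no detectable overdispersion) `M` is reported
at the cap. Heterozygotes are called at RA posterior > 0.99.

The imbalance test estimates the reference ratio `rho` by maximum
likelihood under the error-corrected beta-binomial (effective
reference probability `rho(1 - 2 eps) + eps`) at hets with coverage
>= 10 and MAF > 0.05. Two p-values are reported:

* `p_lrt`: the likelihood-ratio statistic for `rho = 1/2` referred to
  chi-square(1). This is exactly 1 at perfect balance — and therein
  lies a problem: read counts are discrete, and the event `k = n/2`
  has probability of a few percent at realistic coverage, so the null
  distribution of `p_lrt` carries an atom at 1 and is *not* uniform.
* `p_value` (primary, used for FDR): the exact two-sided tail of the
  balanced beta-binomial with the standard mid-p correction (half the
  boundary mass). Because the LRT is monotone in `|k - n/2|` at fixed
  `n`, this is the exact finite-sample version of the same ordering,
  and the mid-p correction removes the discreteness atoms; its null
  distribution is close to uniform, which is what q-value estimation
  downstream assumes.

Sample-level QC is advisory: a sample fails when `M < 20` (gross
overdispersion, e.g. pooled individuals), when the mode of the het
allelic-ratio distribution deviates from 1/2 by more than 0.1
(chromosomal abnormalities such as 3:1 copy-number skews), or when the
all-SNP ratio histogram lacks its three expected peaks (near `eps`,
1/2, and `1 - eps`; the trimodality score is the smallest region peak
relative to the global maximum, threshold 0.02). All three thresholds
are configurable; known aberrant samples are better excluded by an
explicit blacklist than inferred.

## Partitioned FDR and motif summaries

ASH p-values are corrected *within* each annotation partition (effect
/ footprint-only / DHS-only) separately, because each partition has a
different prior fraction of true signals: `storey_pi0()` uses the
lambda-grid estimator with a cubic-polynomial smoother evaluated at
the largest lambda (clipped to [0, 1]; partitions under 100 tested
p-values fall back to `pi0 = 1` with a warning), and `qvalues()` is
the step-up transform `min_{j>=i} pi0 * n * p_(j) / j`. ASH
discoveries are SNPs at q < 0.20 in any partition.

Motif-wise ASH enrichment is the motif's ASH fraction over the global
fraction, with a two-sided binomial test against the global rate
(two-sided because depletion is as informative as enrichment) and a
95% Wilson interval on the motif proportion scaled by the global rate;
motifs with <= 100 hSNPs are excluded. The binding-effect regression
`logit(E) ~ C + F + T + N + P` (footprint likelihood ratio, MAF, TSS
distance, tissue count, conservation) is an ordinary `glm` fit with a
ridge-stabilised IRLS fallback under separation.

## Selection on binding sites

Orthologous site sequences are compared in motif coordinates with the
human-fitted prior: a divergent site is *functional* when
`|beta1 * (S_human - S_ortholog)| >= 3` (the interspecies analogue of
the effect-SNP rule, applied to the orthologous sequence with the
human-fitted coefficients), *silent* otherwise; polymorphic sites are
classified by the effect-SNP rule on their two alleles. The per-motif
selection score is `log2((D_f + 0.5)/(D_s + 0.5)) -
log2((P_f + 0.5)/(P_s + 0.5))` with a Haldane pseudocount of 0.5 —
the log2 odds-ratio form matching the two axes of the
divergence-vs-polymorphism plane — plus Fisher's exact p per motif and
Benjamini–Hochberg q across motifs (motifs with fewer than 100
classified sites are dropped). Derived-allele-frequency (DAF)
enrichment is the joint bin proportion over the product of its
marginals; DAF polarity must come from the input (an AA field or
simulation truth), never inferred.

## What the synthetic data emulate — and what they do not

The generators are first-class, tested code, deterministic under a
seed:

* `simulate_genome`: i.i.d. background with non-overlapping planted
  PWM draws (one per genome bin, random offset and strand). Default
  example motif: 10 bp, 8 highly informative columns — informative
  enough that a single substitution at a sharp column shifts the prior
  log odds past the effect threshold under the default prior.
* `simulate_cut_matrix`: the generative mirror of the mixture model.
  Defaults `beta = (-9, 0.8)` give roughly 30% bound sites on planted
  scores; `mu1 = 100, size1 = 4` vs `mu0 = 10, size0 = 2`.
* `simulate_allele_counts`: true ratio
  `rho = 0.5 - a + 2a * sigmoid(kappa * delta)` (amplitude `a = 0.4`),
  coupling the allelic skew to the predicted binding difference
  `delta`; `kappa = 0` is the exact global null. Coverage follows a
  left-truncated negative binomial (`mu = 100`, `size = 5`,
  minimum 10; truncation by resampling, not clamping), emulating deep
  sequencing at DNase hypersensitive sites — at shallower coverage the
  discreteness of read counts puts a floor of several percent under
  any uniformity statistic, so the calibration properties the tests
  assert are statements about well-covered sites.
* `simulate_divergence`: each site is identical, fixed-divergent or
  polymorphic; functional fractions among changed sites are set by the
  regime (neutral equalises at 0.3; positive raises the divergent
  fraction to 0.6; purifying lowers it to 0.1 and skews the
  functional-polymorphism DAF toward rare alleles). Crucially the
  generator *realises* each class with an actual substitution chosen
  by its score shift, so the MK pipeline is exercised end to end
  through sequence classification, not on bare counts.

Deliberately not emulated: linkage disequilibrium, chromatin domain
structure, mappability and PCR-duplicate artefacts, read-level
sequences, enzyme sequence bias in the cut profile, and multi-sample
genotype sharing. Passing tests therefore demonstrate correctness of
the inference given the model, and calibration under the model's own
assumptions — not robustness to the full messiness of real DNase-seq
data.

## Problem sizes and reproducibility

The test suite and `scripts/acceptance.R` run at desk scale: 2,000
sites for mixture recovery, 10,000 SNPs for ASH calibration and
direction concordance, 10,000 p-values for pi0 recovery, and 100–200
motifs at 500 sites each for the selection statistics; the full suite
completes in a couple of minutes on one CPU. Every stochastic step
takes an explicit seed, generators restore the caller's RNG state, and
identical configurations produce byte-identical output files.

## Known limitations

* The activity Z is a Wald statistic from the final IRLS weights; it
  is well behaved in null and permutation simulations but is not an
  exact likelihood-ratio construction.
* The single-`eps` error model ignores coverage-stratified error
  rates; the genotyping interface isolates the likelihood so a
  stratified model could be swapped in.
* Footprint shape is shared across all sites of a motif; protein-level
  heterogeneity (e.g. cofactor-dependent profiles) is out of scope.
* The ortholog comparison assumes pre-aligned, equal-length site
  sequences; misaligned orthologs are dropped and counted rather than
  re-aligned.
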