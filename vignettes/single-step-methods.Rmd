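---
title: "Single-step genomic evaluation with stepblup: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-step genomic evaluation with stepblup}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepblup)
```

## The problem

Reproductive traits in smallholder livestock populations — the motivating
case is age at first calving (AFC, months) and calving interval (CI,
days) in water buffalo — are recorded on modest numbers of animals, with
an incomplete pedigree and an even smaller genotyped subset.  `stepblup`
implements the standard analysis chain for such data:

1. marker and animal quality control,
2. variance-component estimation for a bivariate animal model by REML,
3. breeding-value prediction by pedigree BLUP (ABLUP) and by weighted
   single-step genomic BLUP (WssGBLUP),
4. a window-variance GWAS (WssGWAS) from SNP effects back-solved out of
   the genomic breeding values, and
5. candidate-gene annotation of significant SNPs with a pleiotropy
   classification across the two traits.

A gene-dropping simulator generates populations with known true breeding
values so that every stage can be validated against ground truth.

## Models

### Animal model and REML

Both traits follow

$$ y = X\beta + Za + \varepsilon, $$

with $\beta$ the contemporary-group effects (herd–month–year analogue),
$a \sim N(0,\, G_0 \otimes K)$ the additive genetic effects and
$\varepsilon$ residuals with trait–trait covariance $R_0$ within animal.
$K$ is the relationship matrix: the pedigree matrix $A$ for ABLUP, the
single-step matrix $H$ for ssGBLUP.  `reml_estimate()` maximises the
restricted likelihood by EM, iterating Henderson's mixed-model equations
(MME):

* the genetic update is $\hat G_0 = (\hat a' K^{-1} \hat a +
  \mathrm{tr}(K^{-1} C^{aa}))/q$ with $C^{aa}$ the animal block of the
  inverse MME coefficient matrix;
* the residual update uses conditional expectations of the residual
  cross-products, so animals recorded for one trait contribute their
  conditional moments for the other.  This makes the iteration a proper
  EM step: the restricted log-likelihood is non-decreasing, which the
  test suite asserts at a $10^{-8}$ float tolerance.

Two numerical accelerations keep EM practical without giving up the
monotonicity guarantee:

* **Canonical transformation.** When both traits are recorded on exactly
  the same animals with the same fixed-effect design, a 2×2 transform
  $Q$ with $Q R_0 Q' = I$ and $Q G_0 Q' = \Lambda$ decouples the traits;
  each iteration then solves two univariate systems of size $q + f$
  instead of one bivariate system of size $2q + 2f$ — the same EM map at
  roughly a quarter of the cost.  The test suite verifies that the
  canonical and general paths agree on both the likelihood and the EM
  update to $10^{-6}$.
* **Guarded extrapolation and AI steps.** The first cycles are
  SQUAREM-type (two EM steps, then an extrapolated jump kept only when
  it does not lower the restricted log-likelihood); after the warm-up,
  the iteration switches to average-information (AI) updates.  The REML
  score comes free from each EM step via the Fisher identity
  ($\partial l/\partial G_0 = -\tfrac12 (q G_0^{-1} - G_0^{-1} S_a
  G_0^{-1})$ with $S_a$ the EM sufficient statistic), and the AI matrix
  is built from matrix-vector products with the stored MME
  factorisation.  AI candidates are step-halved until the likelihood
  does not decrease and are restricted to well-conditioned covariance
  matrices (|correlation| at most 0.995 — the likelihood is numerically
  unreliable at the singular boundary); when no candidate qualifies the
  plain EM update is taken.  Every accepted step therefore keeps the
  log-likelihood monotone, while convergence typically takes about ten
  iterations instead of EM's hundreds.

Convergence is declared when the largest parameter change, normalised by
the phenotypic covariance scale $\sqrt{p_{ii} p_{jj}}$, falls below
`tol` (default $10^{-8}$), or when the absolute log-likelihood gain of
an EM step falls below `tol`.  The normalisation matters at the boundary: a
heritability estimate collapsing towards zero would never satisfy a
*relative*-change criterion on the vanishing component itself.
Covariance updates that leave the positive-definite cone are bent back
by an eigenvalue floor at $10^{-8}$ of the largest eigenvalue.

Standard errors come from the average-information matrix evaluated at
the optimum (six parameters in the bivariate case), inverted and
propagated to $h^2$ and $r_g$ by the delta method.  The source reporting
style this package mirrors gives SEs for $h^2$ only and does not state
its SE method; ours is therefore a documented choice, checked against a
finite-difference Jacobian in the tests, not a reproduction.

### Relationship matrices

* `build_A()` uses the tabular recursion with inbreeding;
  `build_A_inverse()` assembles $A^{-1}$ directly from Henderson's rules
  with Mendelian-sampling variances $d_i = \tfrac12 - \tfrac14(F_s +
  F_d)$, inbreeding coefficients by the Meuwissen–Luo traversal, and the
  convention $F = -1$ for an unknown parent so one formula covers all
  parent configurations.  An oracle suite checks $A^{-1} A = I$ on
  random inbred pedigrees.
* `build_G()` is the weighted VanRaden matrix $G = ZDZ'/\phi$, $\phi = 2
  \sum_i p_i(1-p_i)$, with missing calls mean-imputed to $2p_i$ before
  centring.  Allele frequencies default to the observed post-QC
  frequencies (the source is silent on this; base-population frequencies
  can be supplied).  Observed-frequency centring makes $G$ exactly
  singular (row sums vanish), which is why
* `blend_G()` forms $\alpha G + (1-\alpha) A_{22}$, default $\alpha =
  0.95$; $\alpha = 1$ disables blending and is used by the tests that
  require the exact GBLUP/SNP-BLUP equivalence.
* `build_H_inverse()` adds $\tau G^{-1} - \omega A_{22}^{-1}$ on the
  genotyped block of $A^{-1}$, defaults $\tau = 1.00$, $\omega = 0.50$.
  The $\tau/\omega$ search that produced those values in the motivating
  study is not re-implemented; they are plain configuration here.

### WssGBLUP and WssGWAS

SNP effects are recovered from the genotyped animals' GEBVs by

$$ \hat s = \tfrac{1}{\phi} D Z' G^{-1} \hat u , $$

which includes the $1/\phi$ factor so that $Z\hat s = \hat u$ exactly
when $G$ is unblended (the factor cancels in all variance-percentage
outputs; a test recomputes the windows with the unscaled formula to show
it).  Weights update as $d_i = \hat s_i^2\, 2p_i(1-p_i)$, renormalised
to sum to the SNP count after every update — an exact contract asserted
in the acceptance suite.  Two weight iterations are the default
(configurable 1–10); the whole loop (rebuild G → H → solve → back-solve
→ re-weight) is `wssgblup()`.

`window_variance()` computes, for each window of `window_size`
consecutive SNPs within a chromosome, the variance across genotyped
animals of the window genomic value $\sum_k z_k \hat s_k$ as a
percentage of $\sigma^2_a$.  Both a sliding scheme (step 1) and a
non-overlapping tiling are provided because published descriptions of
this procedure alternate between 10-SNP methods text and 5-SNP figure
captions; the default is 10-SNP sliding, and the QTL-detection study
ranks non-overlapping windows so that one strong QTL cannot occupy
several top ranks with copies of itself.  The conventional significance
rule — windows explaining at least 10% of the additive variance — is
implemented as an inclusive threshold in `significant_windows()`; the
pipeline's reporting default is 1% because on desk-scale maps a 10%
rule returns almost nothing outside planted-QTL simulations.  Both are
thresholds on the same table, and the choice is exposed in
`pipeline_config(threshold_pct = )`.

### Evaluation comparison and annotation

`compare_evaluations()` reports, per animal subset (all, bulls, dams,
top 20% overall and within sex, ties broken by animal id):

* CORR — the Pearson correlation of paired breeding values by default.
  The source text is ambiguous about whether its correlations pair
  breeding values or accuracies; both are implemented
  (`corr_on = "bv"` / `"accuracy"`) and the output labels which was
  used.
* %bias reduction — $(\overline{EBV} - \overline{GEBV}) /
  |\overline{EBV}| \times 100$.
* %accuracy increase — $(\overline{Acc}_{GEBV} - \overline{Acc}_{EBV}) /
  \overline{Acc}_{EBV} \times 100$, with PEV-based accuracies
  $\sqrt{1 - PEV/((1+F_i)\sigma^2_a)}$.  A validation-based accuracy
  (masking later phenotypes) is deliberately out of scope; the PEV-based
  definition is the documented assumption.

`annotate_candidates()` maps significant SNPs to genes within 50 kb
(inclusive at exactly 50,000 bp), with signed distances — negative when
the gene lies at lower coordinates than the SNP, zero when the SNP falls
inside the gene span (1-based inclusive coordinates throughout).  A gene
hit by significant SNPs of both traits is flagged pleiotropic.  Gene
tables are local files (TSV or minimal GFF3); no network retrieval.

## The synthetic-data generator

`sim_config()` defaults describe the population the package is aimed at:
a three-generation pedigree of ≈2,850 animals (713 founders, 4.8% of
non-founders with unrecorded parents), ≈36% of animals phenotyped for
both traits, ≈16% genotyped, and two traits with means/SDs 46.31 ± 10.01
and 520.87 ± 103.68, heritabilities 0.36 and 0.051, genetic correlation
0.495.  The residual correlation default 0.513 is derived so the implied
phenotypic correlation is ≈0.467.  The SNP map defaults to 3,000 markers
on 10 chromosomes — a deliberate scale-down of a ~31k-SNP array that
keeps G well-conditioned at desk scale without changing any algorithmic
path.  Contemporary groups are assigned uniformly at random
(`n_contemporary_groups = 30`, effect SD half a phenotypic SD); no
group-size distribution was available to emulate, so uniform assignment
is the neutral choice.

True breeding values are a QTL genomic value plus an infinitesimal
polygenic remainder bred down the pedigree (parent average +
Mendelian-sampling deviation scaled by $\tfrac12 - \tfrac14(F_s+F_d)$),
with a configurable variance split (`qtl_variance_fraction`, default
0.3 over 30 QTL).  Both components are rescaled per trait so the
realized population variance of the TBVs equals the target
$\sigma^2_a$ — the usual calibration in simulation studies; rescaling
preserves the relationship-structured covariance up to a constant.
`qtl_equal_variance = TRUE` instead forces every QTL to carry an equal
variance share, which the GWAS detection study uses to plant QTL of
known size.

What the generator does **not** emulate: linkage (SNPs segregate
independently, so windows smooth noise but cannot be tuned to an LD
decay curve), selection across generations, non-additive effects,
genotyping-array ascertainment, and age/parity structure in the traits.
Passing tests therefore demonstrate the correctness of the machinery on
data satisfying the model's assumptions, not robustness to every
real-data violation of them.

## Validation studies and their problem sizes

The test suite ends with property-based acceptance studies; sizes were
chosen so the whole suite runs on one CPU at desk scale:

* A-inverse oracle: 50 random pedigrees with inbreeding loops, up to 200
  animals, product with tabular A within $10^{-8}$ of identity.
* Single-step degeneracy: with $G := A_{22}$, $\tau = \omega = 1$ (or an
  empty genotyped set), H-based and A-based evaluations agree to
  $10^{-10}$.
* GBLUP/SNP-BLUP equivalence: 50 animals × 200 SNPs, unblended G, unit
  weights; GEBVs match ridge SNP solutions with $\lambda = \phi
  \sigma^2_e/\sigma^2_a$ within $10^{-6}$ and $Z\hat s = \hat u$ within
  $10^{-8}$.
* REML recovery: 30 replicates of a 1,400-animal pedigree with 1,000
  phenotyped animals at $h^2 = (0.36, 0.051)$, $r_g = 0.495$
  (pure-polygenic architecture); replicate means of $\hat h^2$ and
  $\hat r_g$ within 3 Monte-Carlo standard errors of truth, and the
  log-likelihood non-decreasing at every iteration of every replicate.
  One thousand phenotyped animals is the largest size that keeps 30
  bivariate REML fits inside a desk-scale run; the Monte-Carlo SE used
  in the check scales accordingly.
* WssGWAS detection: 30 replicates, 2,000 SNPs on 10 chromosomes, a
  750-animal population with every animal recorded and a random
  500-animal genotyping panel (genotyped animals nested within the
  phenotyped set, as in the motivating study design), three
  equal-variance QTL totalling 45% of $\sigma^2_a$ ($h^2 = 0.4$); after
  two weight iterations, all three QTL-containing windows rank in the
  top 5 non-overlapping 10-SNP windows in ≥80% of replicates.
* Directional evaluation property: 30 replicates of a 300-animal
  population with a 40% genotyped panel; the accuracy-increase metric is
  positive for the genotyped subset in ≥80% of replicates, and the three
  comparison formulas reproduce hand-computed toy values exactly.
* QC and annotation fixtures: a hand-enumerated 10-animal × 12-SNP QC
  fixture (exact survivor sets, idempotence) and exhaustive boundary
  checks of the 50 kb rule and pleiotropy flags.

`scripts/acceptance.R` re-runs scaled versions of these studies plus a
full pipeline on a synthetic population and writes the resulting
quantities as JSON.

## Numerical and design notes

* All MME solves are dense Cholesky factorisations with explicit
  inverses where PEV is needed; the intended scale is up to roughly 10k
  animals.  Sparse/iterative solvers and large-scale H approximations
  (APY) are out of scope.
* QC order is animal call rate → duplicates → SNP call rate → MAF →
  Mendelian conflicts, with "MAF > 5%" strict and "call rate ≥ 90%"
  inclusive, read literally from the usual phrasing.  The five-stage
  pass repeats until a fixed point so that `qc_filter()` is idempotent;
  per-pass removal counts are reported for auditability.
* Duplicate detection keeps the earlier-listed animal (concordance >
  0.99 on ≥100 shared calls); the Mendelian filter uses opposing
  homozygotes in parent–offspring pairs with zero tolerance by default.
  Both rules are stated choices where the convention is unspecified.
* Unknown parents are genuinely unknown everywhere: masked pedigree
  links draw founder alleles in the gene dropper and enlarge the
  Mendelian-sampling variance in the polygenic recursion, consistently
  with the $F = -1$ convention in $A^{-1}$.
* The pipeline (`run_pipeline()`) writes every stage as tab-separated
  text plus a JSON manifest (config snapshot, output checksums) and
  resumes from the first stage whose outputs are missing.

## Limitations

Beyond the generator's simplifications listed above: single records per
animal (no repeated-records or permanent-environment effects), at most
two traits, no maternal effects, no Bayesian alternatives, and
validation-style (forward) accuracy is not implemented.  The REML SEs
are asymptotic; at boundary estimates (heritability near zero) they
should be read with the usual caution.
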