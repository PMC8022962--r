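---
title: "Multiple-testing procedures and empirical FDR evaluation for GWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple-testing procedures and empirical FDR evaluation for GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwasfdr)
```

## The problem

A genome-wide association study (GWAS) tests millions of common variants for
association with a trait. The conventional answer to this multiplicity is a
fixed significance threshold of $P < 5\times10^{-8}$, a Bonferroni-style
correction for roughly one million independent common-variant tests that
controls the family-wise error rate (FWER). FWER control is deliberately
strict: it protects against even one false positive, and in large modern
studies it leaves many real associations undetected.

This package implements and evaluates the alternatives on equal footing:

* **Fixed P-value thresholds** ($5\times10^{-8}$, $5\times10^{-7}$,
  $5\times10^{-6}$, ...) and Bonferroni control, optionally with an
  effective number of independent tests (`fixed_threshold()`,
  `bonferroni()`).
* **False discovery rate (FDR) control** with the Benjamini–Hochberg (B–H)
  and Benjamini–Yekutieli (B–Y) step-up procedures (`fdr_bh()`,
  `fdr_by()`), adapted to GWAS by LD clumping (below).
* **Bayesian FDR control** through the Wakefield approximate Bayes factor
  and the Bayesian false discovery probability (`abf()`, `bfdp()`,
  `fdr_bayes()`).
* **Multi-trait testing**: metaMANOVA joint statistics, a multivariate
  Bayes factor, and Bonferroni-adjusted parallel univariate tests
  (`meta_manova()`, `multivariate_abf()`, `univariate_multi_trait()`).

Every procedure is judged by its *empirical FDR* (eFDR): rejected loci are
labeled true or false positives against a truth set, and
eFDR $= V/(V+S)$, with the convention that an empty rejection set has
eFDR 0.

## Loci, not variants: the clumping adaptation

Linkage disequilibrium (LD) makes neighbouring variants highly correlated,
so GWAS discoveries are counted as *loci* — clusters of correlated nearby
variants summarized by their most significant (lead) variant. Step-up FDR
procedures are not closed under taking a subset of rejections, and the
positive-dependence assumption behind B–H is doubtful on the full variant
set, so the package follows the locus-adapted recipe: first greedily clump
*all* tested variants into loci (`clump()`: repeatedly take the smallest-P
unassigned variant as a lead and absorb every unassigned variant on the
same chromosome within 1 Mb with dosage $r^2 > 0.1$ against the lead), then
run the step-up procedure on the lead-variant P-values (or BFDPs) only.
Fixed P-value thresholds instead clump just the significant variants, which
yields the same loci for the variants that pass. `evaluation_table()` and
`run_replicates()` apply the regime appropriate to each procedure.

Ties in P are broken by chromosome, position and id, so a clump is a
deterministic function of its input. The window is measured lead-to-member
and is inclusive; LD is computed in-sample from a dosage matrix
(`ld_source()`), and loci never span chromosomes.

## The Bayesian machinery

For variant $j$ with effect estimate $\hat\theta_j$, sampling variance
$V_j = se_j^2$ and a normal prior $N(0, W)$ on the effect, the approximate
Bayes factor is
$$\mathrm{ABF}_j = \frac{1}{\sqrt{1-r_j}}\exp\!\left(-\tfrac{1}{2}Z_j^2 r_j\right),
\qquad r_j = \frac{W}{V_j + W},$$
the ratio of prior predictive densities under the null and the alternative
— small values are evidence against the null. With prior odds
$PO = (1-\pi_1)/\pi_1$ of no association,
$$\mathrm{BFDP}_j = \frac{\mathrm{ABF}_j \times PO}{\mathrm{ABF}_j \times PO + 1}$$
approximates the posterior probability of no association, and the Bayesian
FDR is controlled by rejecting the $k$ smallest BFDPs with
$\bar{\mathrm{BFDP}}_{(1..k)} \le \alpha$ (`fdr_bayes()`).

Parameter choices that matter:

* **$W$** (prior effect variance, trait-SD$^2$ per allele): default 0.04,
  i.e. a prior effect standard deviation of 0.2 trait-SD — a conventional
  weakly-informative choice for quantitative traits; it is a per-study
  setting (`W` argument throughout).
* **$\pi_1$** (prior association probability): estimated conservatively as
  the proportion of tested variants with $P < 5\times10^{-8}$
  (`estimate_pi1()`). In underpowered studies this can be zero, which would
  make $PO$ infinite, so the estimate is floored at $1/(10m)$ with a
  warning. The alternative estimator — clumped genome-wide-significant
  locus count divided by one million independent common variants — is
  available as `method = "loci_per_million"`.
* Effect sizes and standard errors missing from public result files are
  reconstructed from $Z$, allele frequency and sample size
  (`reconstruct_effects()`):
  $se = 1/\sqrt{2p(1-p)(n + Z^2)}$, $\beta = Z \cdot se$. **This assumes a
  variance-standardized (inverse-normalized) trait**; it is the one place
  the package assumes a trait scale.

For $L$ correlated traits, the joint null of no association with any trait
is tested with $t = z^\top\widehat\Omega^{-1}z \sim \chi^2_L$, where
$\widehat\Omega$ is the correlation of the trait $Z$-scores estimated from
approximately-null variants ($\max|Z| < 2$;
`estimate_trait_correlation()`). The multivariate Bayes factor uses an
independent standardized-effect prior with common variance $W$, i.e. a
density ratio $N_L(z; 0, \widehat\Omega) / N_L(z; 0, \widehat\Omega + WI)$
— with $L = 1$ it reduces exactly to the univariate ABF on the $Z$ scale.
The literature leaves the exact multivariate prior open (correlated vs
independent effects); the independent-prior form was chosen for its
transparency and its exact $L=1$ consistency.

## Truth sets and eFDR evaluation

For empirical data the package adopts the sequential-meta-analysis design:
the largest, most recent study of a trait is the approximate truth, the
earlier smaller study is the test set. After harmonization
(`harmonize()`: intersect on variant id, align effect alleles by flipping
swapped rows, drop irreconcilable ones) and a MAF $> 5\%$ filter
(strict inequality), `build_truth()` records the truth study's
genome-wide-significant variants, and `label_loci()` labels each rejected
test locus:

* `ld_strict` (default): true positive iff the lead has $r^2 > 0.80$ with
  *any* truth variant at $P < 5\times10^{-8}$;
* `ld_relaxed`: $r^2 > 0.60$ and truth $P < 5\times10^{-7}$;
* `distance`: lead within $\pm$50 kb of such a truth variant.

Matching consults any sufficiently significant truth variant, not only
truth locus leads — the lead of a genuinely detected locus need not be the
truth study's lead. A lead that is itself truth-significant matches itself
($r^2 = 1$). LD matching is restricted to the lead's chromosome.

`compare_thresholds()` turns two nested evaluations into the
"$\Delta$ significant loci (% true)" bookkeeping used to quantify what a
relaxed threshold buys.

## The simulator

`sim_config()` + `make_paired_studies()` / `run_replicates()` generate
fully known ground truth:

* **Genotypes** (`simulate_genotypes()`): $M$ variants in independent
  blocks; per block, $2n$ haplotypes from a latent AR(1) Gaussian
  (parameter $\rho$) thresholded at each variant's target MAF quantile;
  dosage = sum of two haplotypes. Within a block, $r^2$ decays with lag;
  blocks are placed $>1$ Mb apart so clumping windows never bridge them.
  This is a deliberately transparent LD model — it reproduces the features
  the procedures under test respond to (blocky LD, MAF spectrum,
  lead/partner ambiguity) but not recombination hotspots, long-range LD,
  or population structure, so passing tests speak to procedure behavior
  under blocky LD, not to every property of real genomes.
* **Architecture** (`assign_effects()`): one causal variant in each of
  `n_causal` randomly chosen blocks, with half-normal effect magnitudes,
  random signs, and $\sum_j 2p_j(1-p_j)\theta_j^2$ normalized to the
  target explained variance `hsq`. The default law (`"truth_sig"`)
  additionally floors each causal's explained variance at the truth
  study's genome-wide detection threshold, $z^2_{5\times10^{-8}}/n_{truth}$:
  in the sequential-meta-analysis design that the simulator emulates,
  causal effects are seeded from a truth study's *significant* variants,
  so a causal the truth study cannot see would contradict the design and
  poison truth-set evaluation. The untruncated law (`"half_normal"`) and
  an explicit effect list (e.g. estimates taken from a reference study)
  are also available.
* **Phenotypes** (`simulate_phenotype()`, `simulate_phenotypes_multi()`):
  $y = \sum_j G_j\theta_j + \varepsilon$, $\varepsilon \sim N(0, 1-h^2)$,
  no covariates; multi-trait residuals $N(0, (1-h^2)\Sigma)$; optional
  rank-based inverse-normal transform.
* **Scans** (`association_scan()`): per-variant OLS with intercept;
  P-values from the $t_{n-2}$ distribution (exact at small $n$,
  indistinguishable from normal at GWAS $n$).
* **Paired studies**: the truth study at `n_truth` is by default simulated
  *analytically* — per block, $E[z] = \sqrt{n}\,R\,\theta^{(std)}$ with
  correlated noise $N(0, R)$, $R$ the in-sample dosage correlation — so a
  truth-scale dosage matrix (e.g. $100{,}000 \times 20{,}000$) is never
  materialized. `truth_mode = "genotype"` scans a real pool instead.

### Default study conditions

The default `sim_config()` is a desk-scale analogue of a lipid-trait GWAS:
$M = 20{,}000$ variants in 200 blocks of 100 ($\rho = 0.95$, MAF uniform on
$(0.05, 0.5)$), 30 causal blocks, $h^2 = 0.05$, $n_{test} = 20{,}000$,
$n_{truth} = 100{,}000$, 200 phenotype replicates on one fixed genotype
pool (matching the fixed-genotype, redrawn-phenotype replicate design).
With 30 loci explaining 5% of variance the mean per-locus non-centrality at
$n = 20{,}000$ is $\approx 33$, which puts typical causal loci near the
genome-wide threshold; the per-replicate detected-locus count (about ten)
is then of the same order as published simulation tables for lipid traits,
which is the calibration the defaults aim for — no attempt is made to match
any published table cell, which would require the original consortium data.
Replicate counts: 200 by default (tests and examples); Monte Carlo standard
errors are reported so the residual noise is visible, and scaling `reps` up
narrows them as $1/\sqrt{reps}$.

In simulation the truth set is the generator's causal variants themselves
(`causal_truth()`), matched under the same criteria — a test lead is a true
positive iff it has $r^2 > 0.8$ with a causal variant. This is stricter
than the empirical truth-study design, where every variant the big study
drags over $5\times10^{-8}$ counts as a match; the strict criterion
deliberately surfaces LD-leakage false positives (a locus led by a
moderate-LD partner of a causal variant, or a satellite locus just below
the clumping $r^2$), the same phenomenon that makes published
strict-matching eFDRs slightly exceed their targets.

## Numerical and design choices

* Fixed thresholds use strict `<` (the "$P < 5\times10^{-8}$" convention);
  step-up comparisons use `≤` as printed in the procedure definitions.
* P-values are kept as stored; quantities derived from $Z$ use normal/t
  tail functions directly, and analytic truth studies floor underflowed
  P-values at the smallest positive double (the $Z$ column carries the
  information).
* Degenerate inputs: constant dosage columns make LD undefined and are an
  error in `ld_r2()` (scan skips them with a message); an empty clumping
  input returns an empty locus set; an empty rejection set has eFDR 0;
  a non-positive-definite trait correlation receives a $10^{-6}$ ridge.
* eFDR aggregation over replicates is the mean of per-replicate ratios
  (FDR $= E[Q]$); the pooled ratio-of-means is also reported
  (`efdr_pooled`) since the two can differ when counts are small.
* Child seeds are derived from the master seed by a counter-based linear
  map kept inside the 32-bit range, so each replicate is independently
  reproducible.

## Known limitations

* The AR(1)-threshold LD model has no recombination-map realism; absolute
  eFDR values depend on LD density around causal variants, so simulation
  results transfer qualitatively, not numerically, to real panels.
* **Lead-P inflation under sparse LD.** Thresholding attenuates the latent
  correlation, so at the default $\rho = 0.95$ adjacent dosages correlate
  at only $r^2 \approx 0.55$ and a clumped locus's members are weakly
  correlated. The lead (minimum) P-value of a *null* locus then behaves
  like the minimum of several nearly independent tests — stochastically
  smaller than uniform — and the locus-adapted B–H step-up over-rejects
  relative to its nominal target at desk-scale locus counts. Real imputed
  panels carry near-perfect proxies (the effective minimum is over ~1–2
  tests), which is why published applications of the adapted procedure
  control their targets while the simulator's B–H rows run high. The
  orderings (B–Y below B–H, Bonferroni ⊆ B–H, dominance per replicate) are
  unaffected, and the BFDP procedure's prior-odds weighting makes it
  robust to this inflation.
* **Two truth conventions.** Simulated studies can be evaluated against
  the bare causal ids (`causal_truth()`, the "known-truth" reading) or
  against a generated truth study (`build_truth()` on
  `make_paired_studies()` output, the sequential-design reading). The
  first is far stricter: a locus led by a moderate-LD partner of a causal
  variant, or a satellite just below the clumping $r^2$, counts as a false
  positive even though it is associated through LD, while the truth-study
  convention confirms it like the empirical design would. Comparisons of
  procedures across sample sizes should use the truth-study convention;
  absolute false-positive accounting against the generator's ground truth
  uses the causal-id one.
* The default null mask ($\max|Z| < 2$) of `estimate_trait_correlation()`
  truncates the tails of the Z distribution, which attenuates the
  estimated trait correlation by a few percent at moderate correlations;
  supply `null_mask` explicitly when the variant set is known to be null.
* The analytic truth study draws block-correlated $Z$ noise; it matches the
  scan distribution to first order but ignores the (tiny at GWAS $n$)
  difference between $t$ and normal tails.
* No binary traits, covariates, population structure or imputation-error
  model; no stepwise conditional analysis or fine-mapping; no
  permutation-based FWER or local-FDR estimation.
* In-sample LD from the provided dosage matrix stands in for an external
  reference panel; with small panels, $r^2$ estimation noise propagates
  into clumping.

## A worked example

```{r, eval = FALSE}
cfg <- sim_config(n_test = 2000, n_truth = 20000, M = 1000, n_blocks = 10,
                  n_causal = 4, hsq = 0.2, reps = 50, seed = 7)
rs <- run_replicates(cfg, procedure_panel(p = c(5e-8, 5e-7), bh = 0.05,
                                          by = 0.05, bfdp = 0.05))
agg <- aggregate(rs)
study_report(agg, ladder = c("p:5e-08", "p:5e-07"))
```

For empirical summary statistics, the same evaluation runs off
`read_sumstats()` + `harmonize()` + `maf_filter()` + `build_truth()` +
`evaluation_table()`; the file reader accepts a configurable column
dialect (`glgc_dialect()` covers the public lipid-consortium headers) and
reconstructs missing effect columns from $Z$, EAF and $n$.
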