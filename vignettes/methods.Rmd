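---
title: "Methods: comparing an aggregate ordinal trait with a latent genetic factor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing an aggregate ordinal trait with a latent genetic factor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sfactor)
```

`sfactor` asks a single design question with two answers: when several
correlated binary items (four suicidal-thought/behaviour questionnaire items)
each have a GWAS, is more genetic signal available in (a) a phenotype-level
ordinal aggregate — the 0–4 count of endorsed items, analysed as one GWAS —
or (b) a latent common factor estimated from the item GWAS themselves? This
vignette documents the models, the tunable parameters, the numerical choices,
and what the synthetic-data generator does and does not emulate.

## The estimation chain

### LD-score regression

For variant $j$ with LD score $\ell_j$ (the sum of squared correlations with
all panel variants, including itself), sample size $N$, and $M$ panel
variants, the polygenic model implies
$E[\chi^2_j] = 1 + Na + \frac{N h^2}{M}\ell_j$. We regress $\chi^2_j$ on
$N\ell_j/M$ with a free intercept (sample overlap and stratification load on
the intercept, so it is always estimated, never constrained), using the
standard two-step weights
$w_j \propto 1/[\max(\ell_j,1)\,(1+N h^2 \ell_j/M)^2]$ seeded by an
unweighted pass. Standard errors are delete-a-block jackknives over 200
contiguous blocks (configurable; reduced with a warning when variants are
scarce). Negative point estimates are reported untruncated — flooring them
would bias every downstream difference test.

The cross-trait version regresses $z_{1j} z_{2j}$ on
$\sqrt{N_1 N_2}\,\ell_j / M$; the slope is the genetic covariance $\rho_g$
and the intercept absorbs sample overlap. `estimate_rg()` computes **all
three** quantities entering $r_g = \rho_g/\sqrt{h^2_1 h^2_2}$ with the same
product-regression estimator on the same variants and blocks, so
`estimate_rg(s, s)` is exactly 1 and the jackknife of the ratio is
internally consistent. `genetic_covariance()` assembles the $k \times k$
matrix $S$ (univariate slopes on the diagonal, pairwise slopes off it) and
the sampling covariance $V$ of $\mathrm{vech}(S)$ from the joint jackknife,
which is what the factor model consumes.

**The chi-square regression guard.** Real-data LDSC removes regression SNPs
with $\chi^2 > \max(80, 0.001N)$ as insurance against single loci of
outsized effect violating the polygenic assumption. That guard is the
default here too (`chi2_cap = TRUE`). At simulation scale it is
counterproductive: with $M = 2\times10^4$ and a 0.5% causal fraction, each
causal variant carries roughly $10^2$ times the per-SNP variance of a
million-SNP GWAS, so genuinely polygenic signal exceeds the cap and h²
recovery is biased downward by almost half. Simulation-scale analyses in the
tests and the acceptance script therefore pass `chi2_cap = FALSE`; the
argument exists precisely so the guard is a property of the data scale, not
of the estimator.

### Stratified enrichment

With annotation memberships $a_{jc}$ and annotation LD scores
$\ell_{jc} = \sum_k a_{kc} r^2_{jk}$, the multiple regression
$E[\chi^2_j] = 1 + N \sum_c \tau_c \ell_{jc}$ yields per-annotation
coefficients; the heritability of annotation $c$ is
$h^2_c = \sum_{j \in c} \sum_{c'} a_{jc'} \tau_{c'}$ and enrichment is
$(h^2_c/h^2)/(M_c/M)$, exactly 1 for the base annotation by construction.
Jackknifed enrichments give per-annotation tests against 1. Collinear
annotation columns abort with the offending names rather than being silently
dropped. The MHC interval (chr6:25–34 Mb; build is the caller's choice) is
excluded by default when positions are available.

### The common-factor model

Given $(S, V)$, the single-factor model
$\Sigma(\theta) = \phi\,\lambda\lambda' + \Theta$ is fitted by diagonally
weighted least squares: minimise
$(\mathrm{vech}(S) - \mathrm{vech}(\Sigma))' D^{-1} (\mathrm{vech}(S) -
\mathrm{vech}(\Sigma))$ with $D = \mathrm{diag}(V)$. Identification fixes the
marker indicator's loading to 1 and estimates the factor variance $\phi$,
giving $2k$ free parameters and $k(k+1)/2 - 2k$ degrees of freedom — 2 for
four indicators, 0 (saturated) for three. Promax rotation, conventional in
this literature, is the identity for one factor and is applied as an explicit
no-op. The optimiser is L-BFGS-B with the analytic gradient, five restarts
from perturbed starts ($\lambda = 0.5$, $\theta = 0.5\,\mathrm{diag}(S)$,
multiplicative log-normal jitter), and an objective tolerance near machine
precision; because the tolerance is tight, an abnormal line-search exit is
accepted when the gradient is numerically zero. Parameter covariances use the
sandwich $(\Delta'W\Delta)^{-1}\Delta'W V W\Delta(\Delta'W\Delta)^{-1}$ with
the full $V$. A negative residual variance at the unconstrained optimum (a
Heywood case) triggers a bound-constrained refit at $\theta \ge 0$ and sets
`heywood_corrected`; the bound mechanism is our choice — the literature names
the correction without specifying one.

**Fit statistics.** The model chi-square is the residual-based statistic
$r'[(I-P)V(I-P)']^{+}r$ with $r$ the moment residuals and $P$ the projection
induced by the DWLS estimator at its optimum. We initially used the plain
full-$V$ quadratic form $r'V^{-1}r$; it is *not* asymptotically
$\chi^2_{df}$ when the estimator is diagonal-weighted — analytically its
expectation at our study scale is 2.65 for $df = 2$, and simulations showed
means near 3. The residual-based form is exactly zero at an exact fit and
calibrated to $df$ in simulation (mean 1.88 over 50 replicates), which is
what a fit statistic must do to be comparable across models. Then
$\mathrm{AIC} = \chi^2 + 2 \times \text{free parameters}$,
$\mathrm{CFI} = 1 - \max(\chi^2_m - df_m, 0)/\max(\chi^2_i - df_i,
\chi^2_m - df_m, 0)$ against an independence model that keeps every
indicator heritable but uncorrelated, and SRMR is the root mean square
difference between the correlation-standardised observed and implied
matrices over unique elements. Note CFI is sample-size sensitive: its
denominator is the misfit of the independence model, so at desk-scale
sampling noise CFI can sit well below 1 even when the factor model is true;
it approaches 1 as the sampling variance of $S$ shrinks. The calibration
tests therefore check mean-$\chi^2 \approx df$ at the study scale and the
CFI $\ge 0.99$ property in a well-powered regime (sampling variance reduced
25-fold). A related printed-df caveat: a three-indicator single-factor model
is saturated ($df = 0$ by the counting rule above); some published tables
print non-zero df for such models, and we report our own formula's value.

`compare_models()` implements a dominance rule — a model is superior only
with lower AIC, lower SRMR *and* higher CFI against every competitor —
returning "indeterminate" with per-criterion winners otherwise.

### Per-SNP factor GWAS

Each variant's standardised effects $\hat\beta_{jt} = z_{jt}/\sqrt{N_t}$
extend $S$ with SNP–indicator covariances $\lambda_t b_j$ under a
SNP$\to$factor regression. Holding the measurement structure at the baseline
optimum, $b_j$ has the closed-form GLS solution
$\hat b_j = (\lambda'\Omega_j^{-1}\lambda)^{-1}\lambda'\Omega_j^{-1}
\hat\beta_j$ with $\Omega_j$ built from the per-SNP standard errors and,
optionally, the cross-trait error correlation implied by the LDSC
cross-intercepts (the default; it falls back to independence when the
implied matrix is not positive definite). We deliberately do not re-estimate
the measurement model per SNP: a single variant's contribution to the
covariance structure is $O(1/M)$, the closed form is exact under
proportional effects, null calibration follows from the GLS variance, and
the genome-wide run stays a vectorised pass rather than $M$ optimisations.
Each SNP is treated independently (no joint multi-SNP model), matching
summary-statistic practice. The effective sample size attached to the output
is $\sum_t N_t \cdot (\text{standardised loading}_t)^2$ — the rationale
for this choice is that downstream consumers (mixture fitting, LDSC) need a
per-SNP $N$, and loadings-squared weighting reflects each indicator's
contribution to the factor; it is configurable by post-hoc replacement of
the `n` column.

### Effect-size distribution and projections

After the three QC filters (allow-list; $Z^2 > 80$ strictly, so the boundary
is kept; sample size below $0.67\times$ the 90th percentile, computed by
linear interpolation on the post-allow-list set — the filters are applied
sequentially in the order stated), the two-component model
$z_j \sim (1-\pi_c)\,N(0, \alpha) + \pi_c\,N(0, \alpha + N_j\sigma^2\ell_j)$
is fitted by maximum composite likelihood over variants, in transformed
coordinates ($\mathrm{logit}\,\pi_c$, $\log\sigma^2$, $\log\alpha$) from
starts over $\pi_c \in \{10^{-4}, 10^{-3}, 10^{-2}, 10^{-1}\}$; standard
errors come from the inverse observed information mapped through the delta
method, flagged unreliable at the $\pi_c$ boundary. LD enters only through
$\ell_j$ in the non-null variance — the full LD-window convolution of the
reference implementation of this model class is out of scope, a fidelity gap
documented here: our generator matches the fitted form, so recovery tests
validate the estimator, not the approximation error on real LD.

Expected discoveries at sample size $N$ are
$M\pi_c\int P(|Z| > z_{\mathrm{thr}} \mid Z \sim N(\sqrt{N}\beta,
\sqrt{\alpha}))\,dN(\beta; 0, \sigma^2)$, evaluated by Gauss–Hermite
quadrature. The integrand contains a power transition whose width shrinks
like $1/\sqrt{N\sigma^2}$, and 64-node quadrature is several percent off in
realistic regimes; the default is 4096 nodes (worst-case relative error
~0.1% across the regimes we checked, verified against the closed-form
marginal in testing). The 95% band re-evaluates the curve over draws from
the asymptotic normal of $(\pi_c, \sigma^2, \alpha)$ truncated to the valid
domain, with equal-tailed quantiles.

### Comparison layer and polygenic scoring

Difference tests are two-sided z tests assuming independent estimates; the
aggregate trait and the factor share samples in the motivating design, so
these tests are anti-conservative there — an optional covariance argument
tightens the variance when an overlap estimate exists. BH-FDR follows the
standard step-up rule; profile concordance is OLS of one trait's external
genetic-correlation profile on the other's, reporting the single-predictor
adjusted $R^2$ (the response defaults to the factor profile; the direction
is configurable because neither choice is canonical).

Polygenic scores are $\sum_j w_j \cdot \mathrm{dosage}_{ij}$ over weight
variants with target-cohort minor allele frequency strictly above 5%
(computed in the target itself), alleles harmonised with sign flips on
swapped pairs, missing dosages mean-imputed, and scores mean-centred.
Shrinkage priors are out of scope; weights are raw effects, optionally
thinned to one variant per LD block by the smallest training p-value — a
documented fidelity gap versus continuous-shrinkage scoring.
Associations use logistic models for binary items (reporting the Nagelkerke
$R^2$ increment of adding the score to the covariate-only model), linear
models for the 0–4 aggregate (reporting incremental adjusted $R^2$, with the
Gaussian-likelihood Nagelkerke increment also shown because both conventions
circulate for ordinal outcomes) and for continuous phenotypes. The covariate
design is age, age², sex×age, sex×age², and ten principal components.

## The synthetic-data generator

The generator defines the study conditions; its defaults are fixed once:

- **LD**: independent blocks with AR(1) correlation $\rho^{|i-j|}$; LD
  scores computed exactly from the generating correlation matrix, never
  estimated. A vector of block $\rho$ (default panels in the tests use
  0.2/0.5/0.8/0.95) supplies the between-block LD-score heterogeneity real
  panels show — with a single uniform $\rho$ the LD scores span a few tenths
  and the regression slope is barely identified.
- **Architecture**: point-normal factor effects, $\pi_c = 0.005$ causal,
  factor $h^2 = 0.076$ (a realistic aggregate-trait heritability scale),
  per-trait loadings around 0.5–1.0, residual genetic variance 0.01, GWAS
  $N = 1.2\times10^5$.
- **Overlap**: the four items come from one questionnaire in one cohort, so
  the default is complete sample overlap (`overlap_fraction = 1`) with
  phenotypic correlation 0.5 between items — plausible for items forming a
  severity scale; both are free parameters because no published value pins
  them down. Overlap enters as cross-trait error correlation
  (overlap × phenotypic correlation), the structure that matters for LDSC
  intercepts, rather than via explicitly shared individuals.
- **Aggregation**: the ordinal score is the count of endorsed items; any
  missing item makes the score missing (complete-responder analysis) —
  counting observed items only would deflate scores for incomplete
  responders.
- **Cohort**: binomial(2, MAF) dosages at independent variants, four items
  thresholded from liabilities sharing one factor, covariates independent of
  genotype, binary effective sample size $4/(1/N_\mathrm{cases} +
  1/N_\mathrm{controls})$ when counts are supplied.

What it does **not** emulate: real LD (long-range, MAF-dependent, ancestry-
specific), case-control ascertainment and liability-scale conversion,
population stratification beyond the $\alpha$ inflation term, genotyping
error, or X-chromosome variants. Passing tests therefore demonstrate that
the estimators recover the parameters of *this* generative family at the
stated scales, not that they are robust to every real-data pathology.

## Problem sizes and determinism

The test suite and acceptance script run at $M = 2\times10^4$ variants
(mixture fitting at $5\times10^4$ independent variants), $N = 10^5$–
$1.2\times10^5$, 50 replicates for LDSC and factor-model calibration, 25 for
mixture separation, $10^3$ for PGS null calibration — sizes chosen so the
full pipeline runs on a laptop in minutes while keeping Monte-Carlo error
well below the tolerances tested. Every stochastic function takes a seed and
derives per-stage substreams deterministically, so identical seeds give
byte-identical outputs end to end.

## Known limitations

- Difference tests assume independent estimates (anti-conservative under
  sample overlap).
- The mixture likelihood is composite (independent-SNP) with LD only in the
  non-null variance.
- The factor GWAS holds measurement parameters fixed at the baseline
  optimum.
- PGS weights are unshrunk; LD-independence is block-argmax thinning.
- CFI at desk-scale precision is systematically below its large-sample
  value; compare models, don't interpret it absolutely.
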