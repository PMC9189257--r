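---
title: "Interrogating cumulative risk indices by restricted least squares"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interrogating cumulative risk indices by restricted least squares}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crindex)
```

## The problem

Developmental and psychiatric epidemiology routinely summarizes a battery of
risk indicators -- dichotomous environmental adversities, or counts of
"plasticity" alleles across SNPs -- as a single *cumulative risk* (CR) index:
the unit-weighted sum of the indicators.  Using the sum instead of the
separate indicators buys parsimony, smaller standard errors and easier
replication, but it silently imposes the hypothesis that every indicator
deserves the same regression weight.  That hypothesis is testable, and this
package implements the machinery for testing it *severely*: fit the least
restricted model the index is nested in, impose the index's implicit equality
constraints explicitly, and let the data complain, constraint by constraint.

## The model

For an outcome $y$ and predictor terms $x_1,\dots,x_p$ the package fits

$$ y_i = B_0 + B_1 x_{i1} + \cdots + B_p x_{ip} + e_i $$

by ordinary least squares, optionally under $q$ linearly independent
restrictions $L\beta = c$ on the slope coefficients.  Everything is computed
from the sufficient statistics (means, SDs on the $N-1$ denominator, and
Pearson correlations), so a published correlation table is as good an input
as raw data: with $M = X'X$ reconstructed from the moments,

$$ \hat\beta_r = \hat\beta - M^{-1}L'(LM^{-1}L')^{-1}(L\hat\beta - c), \qquad
   \mathrm{SSE}_r = \mathrm{SSE} + (L\hat\beta-c)'(LM^{-1}L')^{-1}(L\hat\beta-c). $$

The number of free parameters is $k = p + 1 - q$ (the intercept counts and is
never restricted), the error degrees of freedom are $N - k$, and the
coefficient covariance is
$\hat\sigma_r^2\,[M^{-1} - M^{-1}L'(LM^{-1}L')^{-1}LM^{-1}]$ with
$\hat\sigma_r^2 = \mathrm{SSE}_r/(N-k)$.  Coefficients tied by an equality
restriction therefore report identical estimates *and* identical standard
errors, exactly as a composite predictor would.

### Per-restriction (Lagrange) tests

Each restriction has a Lagrange multiplier
$\lambda = (LM^{-1}L')^{-1}(L\hat\beta - c)$ with
$\mathrm{Var}(\lambda) = \hat\sigma_r^2 (LM^{-1}L')^{-1}$, and the ratio
$t = \lambda_j / SE(\lambda_j)$ on $N - k$ degrees of freedom tests whether
that single constraint harms the model.  Two conventions deserve explicit
statement, because software differs:

* the multiplier variance uses the **restricted** model's mean square (the
  convention of SAS `PROC REG` `RESTRICT`, against which the implementation
  was validated cell-by-cell on the published reanalysis);
* equality chains such as `A = B = C` expand to consecutive-difference rows
  `(A - B = 0, B - C = 0)` in declaration order, with the sign written
  (earlier term) minus (later term).

A consequence worth knowing: for a single restriction the squared Lagrange
$t$ and the nested-model $F$ (next section) scale the *same* SSE increase by
*different* mean squares -- $t^2 = \Delta\mathrm{SSE}/\hat\sigma_r^2$ versus
$F = \Delta\mathrm{SSE}/\hat\sigma_f^2$.  They agree closely when the
restriction is nearly true and can differ substantially when it is badly
violated (the restricted mean square is then inflated).  The exact identity
the package's tests assert is $t^2\hat\sigma_r^2 = F\hat\sigma_f^2 =
\Delta\mathrm{SSE}$; treating $t^2$ and $F$ as interchangeable to numerical
precision is not supported by either convention that reproduces the published
tables.

### Nested-model comparison

Models are compared with the classical $F$ for nested regressions,

$$ F(d_1, d_2) = \frac{(R^2_{\text{full}} - R^2_{\text{restricted}})/d_1}
                      {(1 - R^2_{\text{full}})/d_2}, $$

with $d_1$ the difference in free parameters and $d_2 = N - k_{\text{full}}$.
Published reports in this area sometimes describe the denominator degrees of
freedom as "N minus the number of slopes", yet all printed denominators count
the intercept as well; the implementation follows the printed values
($d_2 = N - k_{\text{full}}$ with $k$ including the intercept) and we flag
the wording discrepancy rather than resolve it.  When one restricted model is
compared against another (one restriction added), the less restricted model
plays the role of "full", e.g. $F(1, 212)$ for the two-group versus
all-equal comparison at $N = 215$ -- the convention that reproduces the
published value.

### The three principles

A restricted model (equivalently, a CR index) is interrogated against the
most general model it is nested in:

1. **Do no harm overall** -- the nested $F$ must be non-significant;
2. **Do no harm in particular** -- no single restriction's Lagrange $t$ may
   be significant;
3. **Do some good** -- advisory only: smaller SEs on shared terms, higher
   adjusted $R^2$, lower Schwarz criterion
   ($\mathrm{SBC} = N\ln(\mathrm{SSE}/N) + k\ln N$).

`principles_report()` recommends acceptance iff principles 1 and 2 both
pass.  Principle 3 never gates the verdict, because a gain in efficiency is
a benefit bought, not a rejection rule.  Per-restriction tests default to
unadjusted two-sided $\alpha = .05$, mirroring standard practice in the
source literature; Holm or Bonferroni adjustment is available behind a flag
but off by default -- fidelity first, hooks for rigor.

## Composites, genotypes, and the G x E ladder

A unit-weight composite entered as one predictor is algebraically identical
-- in $R^2$, SSE, intercept, shared coefficient and SE, adjusted $R^2$ and
SBC -- to entering its sources separately under an all-equal restriction.
`check_composite_equivalence()` verifies this numerically on any dataset,
including the moderated case where composite-by-environment and
source-by-environment product terms carry matching equality chains.

SNP allele counts (0/1/2 plasticity alleles) decompose via `code_snp()` into
a dominant code (any allele present) and a recessive code (both present);
the codes sum back to the count, so a gene-total CR index equals the sum of
all dominant and recessive codes, and the identity above applies to the
per-SNP representation.  `build_gxe_ladder()` assembles the
differential-susceptibility model sequence: main effects, added G x E
product, the strong-susceptibility restriction (environment main effect
zero), and additionally a zero gene main effect.  Because the environment is
mean-centered *before* products are formed and products are never
re-centered, the zero-gene restriction is a test of the gene effect at the
mean environment.  Covariates such as a 0/1 sex indicator are entered as
given, never centered, so intercepts keep their natural interpretation.

## Synthetic data: what it emulates and what it does not

Three seed-deterministic generators make every pipeline stage testable
without access to the original raw records (which were never deposited):

* `exact_moment_sample()` constructs a table whose sample moments equal a
  target *exactly* (orthonormalized noise rotated by a square root of the
  target correlation matrix), so summary-path and raw-path fits can be
  compared to numerical precision.
* `simulate_risk_indicators()` draws correlated dichotomous indicators from
  a latent-threshold normal model.  The latent route (rather than
  independent Bernoullis) is the default because real risk batteries show a
  positive manifold; the default exchangeable latent correlation of .45 was
  chosen once to put the induced indicator correlations in the range of the
  packaged environmental-risk table (mostly .1-.6), and default prevalences
  equal that table's indicator means.  Default outcome weights (-8.6 on the
  first four indicators, -1.43 on the rest), intercept 114.9 and residual SD
  12.7 reproduce the scale of the published two-group solution (outcome SD
  near 18, $R^2$ near .5).
* `simulate_gxe()` draws SNPs independently as Binomial(2, freq) --
  Hardy-Weinberg, no linkage, no gene-environment correlation, matching the
  near-zero cross-SNP and gene-environment correlations of the published
  genetic tables; default allele frequencies (.19, .19, .74, .49, .58) are
  the published per-SNP index means divided by two, the environment matches
  the published hostility scale (mean 3.63, SD 1.43), and the default
  strong-susceptibility truth sets both main effects to zero with a G x E
  slope of 0.07 on the gene-total scale and residual SD 1.5 (outcome SD near
  the published 1.65).

What the generators deliberately omit -- and what passing tests therefore do
*not* establish about real data: linkage disequilibrium, population
stratification, gene-environment correlation, missing data, measurement
error in the environment, and any non-normal outcome noise.  The
latent-threshold model also fixes tetrachoric-style dependence; real
indicator batteries can be dependent in other ways.

## Numerical choices

* All solves use a symmetric (Cholesky) factorization of $M$; the predictor
  cross-product block is rejected above condition number `1e12`, with a
  pivoted-QR diagnostic that names a linearly dependent column subset.
* Correlation inputs must be symmetric to `1e-10`; lower-triangle input is
  mirrored.  A smallest eigenvalue in `[-1e-8, 0)` warns (typical of
  published tables rounded to two decimals, which are otherwise taken at
  face value -- no smoothing); below `-1e-8` is an error.
* Restriction systems are checked for rank: contradictory rows (same
  combination, different constants) raise an infeasibility error, duplicate
  rows a redundancy error naming the row.
* Restricting a coefficient to its own unrestricted estimate is exact: SSE
  is unchanged and the multiplier is zero to rounding.
* Missing values are disallowed in modeled columns; listwise deletion is
  available behind an explicit flag and logs the dropped count.
* p-values come from the Student-t and F distributions (equivalently, the
  regularized incomplete beta function).

## Problem sizes used by the test suite

The suite exercises the identities at sizes chosen to keep the full run
comfortably under a minute of fitting time while covering the regimes that
matter: fuzzed equivalence and oracle checks at $n$ from 30 to 500 and 2-12
predictors (over a hundred replicates), a 500-replication type-I-error study
of the equal-weights test at $n = 200$, and single large-sample parameter
recovery runs at $n$ = 20,000-50,000 where closed-form frequencies and
generating coefficients are recovered within three standard errors.

## Known limitations

Weighted or generalized least squares, robust standard errors, inequality
constraints and Bayesian estimation are out of scope, as are polychoric
correlation estimation, survey weighting, multiple imputation, GWAS-scale
polygenic weighting, haplotype phasing, and estimation of weak-susceptibility
crossover regions.  Automatic dichotomization of quantitative indicators is
deliberately not offered: cut-points must be supplied explicitly, and
quantile-based cuts warn about their sample specificity.
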