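---
title: "SNP-set association tests: models, simulation design, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SNP-set association tests: models, simulation design, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpsetr)
```

`snpsetr` tests whether a *set* of SNPs — typically a gene region — is
associated with a binary disease outcome, and ships a simulation engine to
measure how well the available tests do so under controlled conditions.
This vignette is the package's account of the statistics it implements,
the choices that were genuinely open, and what its synthetic benchmarks do
and do not demonstrate.

## The three tests

### Logistic kernel machine score test

For individual $i$ with outcome $D_i \in \{0,1\}$, covariates
$x_{i1},\dots,x_{im}$ and additive dosages $z_i \in \{0,1,2\}^p$, the
model is

$$\operatorname{logit} P(D_i = 1) = \alpha_0 + \sum_m \alpha_m x_{im} + h(z_i),$$

where the set effect $h(\cdot)$ lives in the function space induced by a
kernel $K(\cdot,\cdot)$ measuring genotype similarity between pairs of
individuals. Treating $h$ as a random effect with mean zero and covariance
$\tau K$ turns "no association" into $H_0\!: \tau = 0$, which is tested by
the variance-component score statistic

$$Q = (D - \hat\mu)^\top K (D - \hat\mu),$$

with $\hat\mu$ the fitted probabilities of the covariate-only logistic
fit. Only the null model is ever fitted; $Q$ costs one quadratic form.
Under $H_0$, $Q \sim \sum_i \lambda_i \chi^2_{1,i}$ with $\lambda_i$ the
eigenvalues of $P_0^{1/2} K P_0^{1/2}$, where
$P_0 = V - VX(X^\top V X)^{-1} X^\top V$ and $V =
\operatorname{diag}(\hat\mu_i(1-\hat\mu_i))$ account for estimating the
covariate coefficients.

Kernels (`kernel_spec()`):

* `linear`: $K(z, z') = \sum_j w_j^2 z_j z'_j$ — the inner product;
  appropriate when effects are additive across SNPs.
* `ibs`: $K(z, z') = \sum_j w_j^2 (2 - |z_j - z'_j|)$ — the count of
  alleles shared identical by state; robust to non-additive structure.
* `linear.weighted`, `ibs.weighted`: per-SNP weights
  $w_j = \operatorname{dbeta}(\text{MAF}_j;\, a_1, a_2)$ with defaults
  $a_1 = 1$, $a_2 = 25$. This density is $\approx 25$ near MAF 0 and
  $1.5\times 10^{-6}$ at MAF 0.5, so the weighted kernels are essentially
  low-MAF detectors; they trade away power on common causal variants.

Three conventions had to be pinned because the definitions leave them
open, and none affects p-values:

* **Weights enter squared** ($K = Z W^2 Z^\top$), matching the convention
  of the kernel-association software ecosystem. Applied uniformly to the
  IBS family as well.
* **No kernel normalization** (no division by $2p$): $Q$ and the
  $\lambda_i$ scale together, so p-values are invariant to positive
  scaling of $K$ (this invariance is a unit test).
* **$Q$ carries no factor $\tfrac12$**: same invariance argument;
  documented so reported $Q$ values are reproducible.

### PCA likelihood-ratio test

Dosages are standardized per SNP to mean 0, standard deviation 1
(denominator $n-1$; the choice of denominator cancels from every test
statistic), so their covariance is the SNP correlation matrix. Its
eigendecomposition gives PCs ordered by explained variance;
`select_k()` keeps the smallest $k$ whose cumulative proportion reaches
the threshold $Z\%$ — the comparison is $\geq$, so if the top 2, 3, 4 PCs
explain 63%, 75%, 80%, then PCA(60%), PCA(70%), PCA(80%) use
$k = 2, 3, 4$. The test is the $k$-df LRT between
`logistic(D ~ covariates + PCs)` and `logistic(D ~ covariates)`.

The threshold is a bias-variance dial, not a nuisance: with one tight LD
block, PC1 already carries the signal and a low threshold wins (extra PCs
only spend degrees of freedom); with several blocks or a causal SNP
outside the main block, only higher thresholds reach the information.
This degrees-of-freedom trade-off is exercised by the power harnesses in
the acceptance tests. PCA is computed on the pooled sample (unsupervised);
selecting PCs by their association with $D$ would invalidate the LRT's
reference distribution, and no such selection is offered.

Determinism conventions: eigenvector signs are fixed (largest-magnitude
loading positive) so `pc_loadings_report()` is reproducible; ties among
eigenvalues keep `eigen()`'s stable order, which cannot affect p-values
because any orthonormal basis of the retained span gives the same LRT.

### Min-p with effective-number-of-tests correction

Each SNP gets a 1-df Wald test from `logistic(D ~ covariates + z_j)`; the
set p-value is $\min(1, k_\mathrm{eff} \cdot p_{\min})$.
$k_\mathrm{eff}$ defaults to a simplified correlation-discount bound,
$k_\mathrm{eff} = 1 + \sum_{j\ge 2} \sqrt{1 - \max_{k<j} r^2_{kj}}$,
which is $p$ for independent SNPs and 1 for perfectly correlated ones; an
eigenvalue-based alternative (`variant = "liji"`) is provided for
sensitivity analysis, since the literature offers several defensible
variants and the exact one behind any given published number is rarely
recoverable. Both keep $k_\mathrm{eff} \in [1, p]$, and both leave the
test conservative under strong LD — Bonferroni-type corrections cannot be
exact for correlated tests, which is precisely the weakness the set tests
exploit.

## The mixture-of-chi-square tail probability

`pvalue_mixture_chisq()` is the numerical core. It evaluates
$P(\sum_i \lambda_i \chi^2_{1,i} > q)$ by inverting the characteristic
function:

$$P = \frac12 + \frac{1}{\pi}\int_0^\infty
  \frac{\sin\theta(u)}{u\,\rho(u)}\,du,\qquad
  \theta(u) = \tfrac12\Big(\sum_j \arctan(\lambda_j u) - qu\Big),\quad
  \rho(u) = \prod_j (1+\lambda_j^2u^2)^{1/4}.$$

The integral is computed by a midpoint rule whose step is chosen from an
aliasing bound (the discretization error equals a sum of far-tail
probabilities of the mixture, pushed below target by construction), and
whose truncation point is monitored by two explicit tail bounds (an
absolute envelope bound and an oscillation/integration-by-parts bound).
Target accuracy is $10^{-6}$; eigenvalues are rescaled by
$\lambda_{\max}$ first, eigenvalues below $10^{-10}\lambda_{\max}$ are
truncated to zero, and p-values are floored at $10^{-15}$. If the sum
fails to converge within its term budget or returns a non-positive value,
a four-moment (skewness/kurtosis-matched) noncentral-chi-square
approximation takes over and the result is flagged `method = "moment"` —
never a permutation fallback in the production path. The test suite
validates the inversion against exact chi-square cases, frozen values
from an independent numerical-convolution oracle, and Monte Carlo.

For linear-family kernels $K = \Phi\Phi^\top$ with $\Phi = ZW$, so the
$\lambda_i$ come from the $p \times p$ matrix $\Phi^\top P_0 \Phi$
instead of the $n \times n$ operator. The same exact trick extends to the
IBS family whenever dosages are integers: the per-SNP similarity matrix
$M_{ab} = 2-|a-b|$ ($a,b \in \{0,1,2\}$) is positive definite, so its
Cholesky factor yields a 3-column-per-SNP feature map and a
$3p \times 3p$ eigenproblem. Both routes are tested to agree with the
dense computation to $10^{-8}$; the dense route remains available
(`path = "dense"`) and is used automatically for fractional (imputed)
dosages under IBS.

Degenerate inputs are defined, not accidental: a constant genotype
column contributes nothing to the projected spectrum (all-zero
$\lambda$ gives $p = 1$), while the weighted kernels refuse monomorphic
SNPs because the Beta weight is undefined at MAF 0; logistic fits detect
complete separation (diverging coefficients with fitted probabilities
pinned at 0/1) and fail loudly rather than report a Wald p-value of a
meaningless fit. In replicated studies those failures become `NA` for
that method and replicate only.

## The simulation engine

`generate_panel()` builds a phased haplotype panel from an `ld_spec()`:
within each block, haplotype alleles share an exchangeable latent Gaussian
correlation $\rho$, and allele $j$ is 1 iff the latent variable falls
below $\Phi^{-1}(f_j)$, with $f_j$ drawn uniformly from the block's
frequency range. This gives direct, testable control over block structure:
the implied allelic $r^2$ between two SNPs has a closed
(one-dimensional-integral) form under the Gaussian copula, and panel
generation verifies the realized mean within-block $r^2$ against it
(tolerance 0.05 for panels of at least 10,000 haplotypes), along with the
realized frequency range (tolerance 0.02). A Li–Stephens-style resampler
with recombination maps was deliberately not built; users with real
phased haplotypes can import them via `read_haplotype_panel()`.

Individuals are two haplotypes drawn with replacement
(`draw_genotypes()`), so genotypes are in Hardy–Weinberg proportions at
panel frequencies (tested at 3 Monte-Carlo SEs). Disease follows the
log-additive model $\operatorname{logit} P(D=1\mid z) = \beta_0 +
\sum_{j \in \text{causal}} \log(\mathrm{RR}_j)\, z_j$, taken at face
value as stated. `calibrate_beta0()` fixes $\beta_0$ by monotone root
finding so the Monte-Carlo prevalence over $10^5$ draws matches a target;
with no causal SNPs the answer is `qlogis(target)` exactly.
**Baseline prevalence defaults to 0.10** — a typical complex-disease
figure; since case-control sampling conditions on outcome status, the
tests' operating characteristics are insensitive to it, and the unit
tests exercise calibration rather than any particular prevalence.
`sample_case_control()` then fills the case and control quotas by
rejection sampling (retrospective design), deterministically given its
seed. `mask_typed()` restricts the analysis to array SNPs, leaving causal
variants typed or untyped as the scenario dictates.

`builtin_scenario()` fixes a small library of study conditions: null
panels of 31 SNPs (one block, 8 typed) and 154 SNPs (two blocks of
119 + 35, 39 typed, roughly one third of them in the second block); a
very-strong-LD null exposing min-p conservativeness; a two-typed-causal
power scenario (RR 1.1 each, typed–causal median $r^2 \approx 0.5$); a
low-MAF causal pair (MAF 0.08–0.15, one typed) where Beta(1, 25)
weighting pays off; and an eight-point LD gradient for power-versus-$r^2$
curves. Panel seeds are fixed inside the library — the panel *is* the
region — while the user seed drives sampling. Default sample sizes are
1000 cases + 1000 controls for power scenarios and 500 + 500 for null
calibration; the test suite runs 1000–2000 null replicates and 1000
replicates per power point, sizes chosen so that binomial standard errors
(about 0.007 at $\alpha=0.05$, $R=1000$) are well inside the effects
being demonstrated.

## What the benchmarks show — and what they cannot

The acceptance suite demonstrates, on these synthetic panels: nominal
type I error of the kernel and PCA tests at $\alpha \in \{0.05, 0.01\}$;
sub-nominal type I error of min-p under strong LD; higher power of the
set tests than min-p with two typed causal SNPs; power increasing in the
causal-to-typed median $r^2$ for every method; and the weighted kernel
overtaking the unweighted one for low-MAF, weakly tagged causal pairs.

Synthetic panels are not real genomes. Exchangeable-block LD has no
recombination-distance decay, no MAF-LD coupling, and no population
stratification; covariates are absent from the simulated studies (the
analysis code supports them and is tested with them separately). Passing
these benchmarks therefore shows the statistics are implemented and
calibrated as specified — it does not certify power numbers for any real
region, which depend on the region's actual LD.

Known limitations:

* The mixture-chi-square null is asymptotic. No small-sample variance
  adjustment is applied; at $n \approx 60$ the test suite measures a
  systematic gap of about 0.01 between the analytic p-value and the exact
  permutation null of $Q$ (binary residuals are not Gaussian at that
  $n$). At the sample sizes the package targets ($n \ge 500$) the
  calibration checks show no such deficit.
* Continuous outcomes, gene–environment interaction kernels, and
  dominance/epistatic disease models are out of scope.
* `k_eff` implements a simplified bound, not the exact
  $\alpha$-dependent exponent of the original derivation; the min-p
  baseline is meant as a comparator, not a recommended test.
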