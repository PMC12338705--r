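---
title: "Models and methods for multi-environment genomic prediction with gxePredict"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for multi-environment genomic prediction with gxePredict}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxePredict)
```

# The problem

Lifespan in panels of fully inbred *Drosophila* lines varies with sex and
rearing temperature, and the genetic effects on lifespan are themselves
environment-dependent. gxePredict implements the model family used to
quantify that structure and to predict line-by-environment phenotypes: a
set of nested kernel (RKHS) mixed models, a Bayesian multi-trait model
that treats the phenotype in each environment as a distinct trait, and a
reaction-norm random-regression model, together with three
cross-validation schemes that probe how information transfers from
observed to unobserved lines, cells and environments.

# Kernels

With $n$ lines, $r$ environments (two sexes $\times$ three temperatures)
and $q = n \times r$ records:

* **G** is the VanRaden genomic relationship matrix,
  $G = WW^\top / (2\sum_j p_j(1-p_j))$, with $W$ the column-centered
  dosage matrix. For fully inbred lines (dosages in $\{0,2\}$) the mean
  diagonal of $G$ is close to 2, twice the outbred value — kept as-is,
  since only the product $\sigma^2 K$ is identified. Variants are first
  filtered at MAF $\ge$ 0.05 and missing rate $\le$ 0.2, and surviving
  missing dosages are imputed to the variant mean (the source data leave
  imputation unspecified; variant-mean imputation is neutral for the
  centered cross-products).
* **E** is the environmental similarity kernel $E = X_qX_q^\top / c$,
  where $X_q$ holds the $c = 2$ record-level covariates (a 0/1 sex code
  and the temperature in deg C), each standardized to mean 0 and
  *population* variance 1 across the records, so a balanced binary code
  maps to exactly $\pm 1$. Any proportionality constant in $E$ trades
  off against its variance component; dividing by $c$ puts the mean
  diagonal at 1. No intercept column enters $X_q$ — the models carry a
  global intercept.
* **ZGZ'** expands $G$ to record level through the 0/1 incidence matrix
  $Z$, and the gene-environment kernel is the Hadamard product
  $ZGZ^\top \circ E$, positive semi-definite by the Schur product
  theorem. PSD is enforced at the line level (an eigenvalue check on
  $G$); mildly negative round-off eigenvalues (above $-10^{-6}$ of the
  largest) would be clipped, anything worse raises an error.

# The RKHS mixed models and REML

The four nested models for a record $y_{ijk}$ are intercept-plus-kernels:
G-BLUP ($ZGZ^\top$ only), E-BLUP ($E$ only), GE-BLUP (both), GxE-BLUP
(both plus $ZGZ^\top \circ E$), each with an iid residual. Variance
components maximize the restricted likelihood
$\ell_R = -\tfrac12[\log|V| + \log(\mathbf{1}^\top V^{-1}\mathbf{1}) +
y^\top P y + (q-1)\log 2\pi]$.

The optimizer is average-information (AI) REML with step halving, a
non-negativity floor, and an adaptive switch to EM-like moves when the
AI step fails — the standard algorithm of mixed-model software in
quantitative genetics, which typically converges in 10–20 inversions of
$V$. If AI fails to converge, a bounded quasi-Newton fallback (L-BFGS-B
on log-variances with analytic gradients) restarts from three
deterministic points (equal split, residual-dominant, kernel-dominant).
Convergence is declared at a relative $\ell_R$ change below $10^{-8}$;
variances below $10^{-10}$ of the total are snapped to exactly zero so
boundary estimates (the "genotypes explain nothing in G-BLUP" case) are
representable. Solves use dense Cholesky factorizations — at the panel
scale this package targets ($q \lesssim 1{,}500$), dense algebra is
faster and simpler than low-rank tricks.

**Variance partition.** The phenotypic variance contributed by component
$k$ is $\sigma^2_k \bar d_k$ with $\bar d_k$ the mean diagonal of its
kernel; PVE normalizes these contributions (residual $\bar d = 1$).
Ignoring $\bar d_k$ would understate the genetic share by roughly half
for an inbred-line GRM.

**Prediction.** BLUPs extend to unobserved records as
$\hat u_k(\mathrm{all}) = \hat\sigma^2_k K_k[\cdot,\mathrm{train}]
\hat V^{-1}(y-\hat\mu\mathbf 1)$, and predictions are
$\hat\mu + \sum_k \hat u_k$.

# The multi-trait model

mvG-BLUP treats lifespan in each environment as one of $r$ traits:
$Y = \mathbf 1 M^\top + A + R$ with $A$ matrix-normal (row covariance
$G$, column covariance $\Sigma_A$) and diagonal residual covariance.
The Gibbs sampler works in the eigenbasis of $G$ (one upfront
eigendecomposition; rows of the rotated $A$ are conditionally
independent), handles missing cells by data augmentation, and draws
$\Sigma_A$ from its inverse-Wishart full conditional.

Priors follow the defaults of Bayesian multi-trait software:
$\Sigma_A \sim \mathrm{IW}(\nu_0 = r + 2,\ S_0)$ with $S_0$ chosen so
the prior mode of each trait's *contributed* genetic variance —
$\Sigma_{A,jj}\times \overline{\mathrm{diag}(G)}$ — equals half the
trait's phenotypic variance (the division by the mean kernel diagonal
mirrors how such software scales its default priors); residual variances
are scaled-inverse-$\chi^2$ with 5 df and mode half the phenotypic
variance. With nearly unrelated lines the split between genetic and
residual variance is weakly identified within a trait, so posterior
summaries of the *diagonal* of $\Sigma_A$ lean on the prior; the
cross-trait covariances are much better identified (they are driven by
within-line cross-environment products). The sampler was validated
against dense grid integrations of the exact posterior on one- and
two-trait instances.

Chain defaults are desk-scale (6,000 iterations, 1,000 burn-in, thin 5),
chosen so a 176-line, 6-trait fit takes well under a minute; the
study-scale chain (300,000 / 200,000 / 50) is available by argument.
All randomness flows through R's RNG, so a seed fixes the chain
bit-for-bit.

Cross-environment genetic correlations are
$r_A = \Sigma_{A,ij}/\sqrt{\Sigma_{A,ii}\Sigma_{A,jj}}$; values below 1
indicate genetic effects that change across environments.

# The reaction-norm model

The random-regression model writes a record as
$y_{ijk} = \sum_t \beta_t \phi_t(x_j) + \sum_t a_{it}\phi_t(x_j) +
\epsilon_{ijk}$ with plain Legendre polynomials $\phi_t$ (the normalized
variant only rescales coefficients), $T = 1$ by default, random
coefficients $a \sim N(0, G \otimes \Sigma_a)$ and a separate residual
variance per environment. The environmental value $x_j$ is the mean
phenotype of environment $j$ over the *training* records, min-max mapped
to $[-1, 1]$.

The record covariance has the convenient form
$V = ZGZ^\top \circ (\Phi\Sigma_a\Phi^\top) + \mathrm{diag}(\sigma^2_{\epsilon,j})$,
optimized by L-BFGS-B over the log-Cholesky factor of $\Sigma_a$ and log
residual variances with analytic REML gradients (fixed-effect design
$\Phi$). Residual variances are floored at $10^{-8}$ of the phenotypic
variance.

For an environment never seen in training the environmental value cannot
be its own observed mean without leaking test information; the default
extrapolation regresses training environment means on the standardized
sex/temperature covariates by OLS, predicts the unseen environment's
mean, and maps it with the training min-max bounds (clipped to
$[-1,1]$). The leaky observed-mean variant exists behind an explicit
argument for replication studies only.

# Cross-validation

Three schemes, 17% test fraction (rounded half-up), 6 replicates drawn
with seeds `seed + k` (replicates are independent draws; the disjoint
6-fold reading of the source design is equally plausible but the
independent one is the default):

* **RandomLines** — whole lines move to the test set with all their
  records; genetic information cannot transfer for them.
* **RandomObservations** — random cells move; every line and environment
  stays represented in training.
* **NewEnvironment** — all records of one sex/temperature cell are held
  out; one deterministic fold per environment, with per-environment
  reporting.

Kernels are built over all records (covariates are design information),
but every estimated quantity — variance components, covariate
standardization, environment means, chains — uses training records only;
a double-fit test with zeroed test phenotypes guards the boundary.
Accuracy is the $R^2$ of the regression of true on predicted phenotypes
(the squared Pearson correlation, affine-invariant); a constant
prediction vector scores 0 with a warning rather than aborting a sweep —
this is exactly what happens to E-BLUP under NewEnvironment, whose
predictions are constant within the single held-out environment.
mvG-BLUP is rejected under NewEnvironment: the model has no intercept or
(co)variance estimates for a trait it never observed.

# The synthetic-data generator

`simulateGenotypes()` draws fully inbred dosages ($\{0,2\}$) with
per-variant MAF uniform on (0.05, 0.5] and redraws monomorphic variants;
`simulatePhenotypes()` draws the four components from the GxE-BLUP
generative model ($a \sim N(0, ZGZ^\top)$; $e = X_q\gamma$ with a single
$\gamma$ draw, so environments act through their covariates;
$ae \sim N(0, ZGZ^\top\circ E)$; iid residual) and rescales each
component so its *realized* sample variance hits its target fraction
exactly (defaults 0.12 / 0.72 / 0.08 / 0.08 of a unit total variance —
the variance composition estimated for the lifespan panel; grand mean 50
days, a typical fly lifespan scale). Empirical scaling makes recovery
tests sharp at the cost of slightly distorting the joint law (components
are only near-orthogonal, so the total variance matches its target
within a few percent, not exactly).

What the generator deliberately omits: linkage disequilibrium,
population structure among lines, within-line replicate flies (records
are line-level means, as in the source design), dominance and epistasis.
Passing tests therefore show correctness of the estimation machinery
under the stated generative model, not robustness to the full
complexity of real panels.

# Problem sizes and numerical choices in the test suite

The acceptance-level checks run the study design at $n = 200$ lines,
$p = 3{,}000$ variants, 6 environments (variance recovery over 20
replicates; all three CV schemes with 6 replicates), the multi-trait
recovery at $n = 300$ with 2 traits, and brute-force oracles (a dense
200$\times$200 REML grid; dense grid integration of the Gibbs
posterior; a 2,000-point random sweep of the RRM likelihood) at small
$n$. Unit tests use smaller panels (12–100 lines) so the full suite
stays fast. Tie-breaking and degenerate-input rules: zero-variance
covariates, all-monomorphic panels, constant predictions, single-environment
gradients and over-filtered genotype matrices all raise explicit errors
(or a defined 0 score) rather than propagating NaNs.

# Known limitations

* The RKHS REML machinery is dense; beyond a few thousand records the
  $O(q^3)$ solves dominate and a low-rank reformulation would be needed.
* With nearly unrelated inbred lines, the within-trait genetic/residual
  split in the multi-trait model is prior-sensitive; genetic
  correlations are robust but their denominators are not fully
  data-determined at $n \sim 200$–300.
* The reaction-norm model inherits the usual caveat that discrete, well
  separated environments are better served by the discrete-environment
  models; it is included for completeness of the model family.
* No LD pruning, variant annotation, or imputation beyond the variant
  mean; no fixed effects beyond the global intercept (sex and
  temperature act through kernels, not design columns).
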