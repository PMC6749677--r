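---
title: "Network-guided multi-trait GWAS: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-guided multi-trait GWAS: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Breeding programs record many genetically correlated traits on the same
material. A multi-trait GWAS (MTM-GWAS) estimates, for each SNP, one effect
per trait under a shared polygenic covariance, which borrows power across
traits but leaves a basic question unanswered: does a locus act on a trait
*directly*, or is its signal *transmitted* through an upstream trait it also
affects? When traits form a recursive system — e.g. shoot biomass driving
water use, and biomass and root mass jointly driving water-use efficiency —
the distinction matters for intervention: selecting on the upstream trait
moves the downstream one, but not conversely.

`semgwas` implements the network-guided alternative in four stages:

1. **MT-GBLUP.** A Bayesian multi-trait genomic BLUP separates each
   phenotype into a genetic value and a residual.
2. **Structure learning.** A directed acyclic graph (DAG) over traits is
   learned from the posterior-mean genetic values by score-based hill
   climbing with bootstrap model averaging.
3. **MTM-GWAS.** Every SNP is tested with a multivariate generalized least
   squares model; its effects are *total* effects.
4. **SEM-GWAS.** The phenotypes are re-modelled as a structural equation
   system over the learned DAG; each SNP effect splits exactly into a direct
   effect plus per-path indirect effects.

# Models

## MT-GBLUP

For \(t\) traits on \(n\) accessions,
\[
\mathbf y = \mathbf X\mathbf b + \mathbf Z\mathbf g + \boldsymbol\epsilon,
\qquad
\mathbf g \sim N(0, \Sigma_g \otimes \mathbf G),\quad
\boldsymbol\epsilon \sim N(0, \Sigma_\epsilon \otimes \mathbf I),
\]
with intercept-only fixed effects and the VanRaden genomic relationship
matrix \(\mathbf G = \mathbf W\mathbf W' / 2\sum_j p_j(1-p_j)\) built from
centered dosages \(W_{ij} = x_{ij} - 2p_j\). Inference is by Gibbs sampling:
flat prior on \(\mathbf b\), independent inverse-Wishart priors on
\(\Sigma_g\) and \(\Sigma_\epsilon\), and multivariate-normal full
conditionals for \(\mathbf b\) and \(\mathbf g\). The sampler works in the
eigenbasis of \(\mathbf G\), where the conditional of the transformed genetic
values factorises over eigencomponents, so one iteration costs
\(O(n\,t^3)\); the core loop is compiled (RcppArmadillo) and uses R's RNG,
making chains bit-reproducible from `set.seed`. Defaults are 25,000 burn-in +
150,000 iterations thinned by 2 (75,000 retained draws). Genomic
correlations and heritabilities are posterior means of the per-draw derived
quantities, with posterior SDs from the same draws.

*Prior hyperparameters* are unavoidable free choices: we use
`df = t + 2` and scale `0.5 * diag(sample phenotypic variances)` for both
covariance priors — proper but weak, centred on an even split of phenotypic
variance. Both are configurable in `mcmc_config()`.

*Rank deficiency.* \(\mathbf G\) from centered markers is singular by
construction; when its smallest eigenvalue falls below \(10^{-8}\) of the
largest we add \(10^{-6}\cdot\overline{\mathrm{diag}(\mathbf G)}\) to the
diagonal. The same rule is applied everywhere a \(\mathbf G\)-inverse is
implied.

*Convergence.* A split-half potential-scale-reduction factor on the variance
draws is reported; values above 1.1 trigger a warning.

## Trait network

Structure learning treats the \(n \times t\) matrix of posterior-mean
genetic values as i.i.d. rows. Each node given its parents is a
linear-Gaussian regression; the network score is
\[
\sum_{v}\Big[\widehat{\ell}_v - \tfrac{k_v}{2}\log n\Big],
\qquad k_v = |\mathrm{pa}(v)| + 2,
\]
i.e. BIC with the intercept and the ML residual variance counted per node
(parameter-count conventions differ across implementations; this one is
fixed and documented). Hill climbing starts from the empty graph and
greedily applies the best single-arc addition/deletion/reversal with a
strictly positive gain; ties break by move type then lexicographic
(from, to), so the search is deterministic. Arc confidence comes from
bootstrap resampling of accessions (default 2,500 replicates): *strength* is
the fraction of replicates containing the edge in either direction,
*direction* the fraction oriented a given way conditional on presence. The
averaged network keeps edges with strength ≥ 0.85 and orients them by
majority direction. Each retained arc is also scored by the change in BIC
when it alone is removed (negative = arc is load-bearing).

The mutual-information independence test that is sometimes paired with
bootstrap structure learning is exposed as an *optional* marginal filter on
arc additions (`mi_alpha`), off by default: hill climbing is score-based and
the interaction between the two is not standardised, so we do not guess a
wiring.

Genetic values are not standardised before structure learning by default
(BIC scores of linear-Gaussian nodes are location/scale equivariant in a way
that only affects the constant, not the search); a caller can scale the
matrix beforehand if desired.

## MTM-GWAS

With plug-in \(\widehat\Sigma_g, \widehat\Sigma_\epsilon\) from the no-SNP
MT-GBLUP (two-stage; refitting components per SNP would be prohibitive),
each SNP \(j\) is tested in
\[
\mathbf y = (\mathbf I_t \otimes \mathbf w_j)\,\mathbf s_j
 + \mathbf Z\mathbf g + \boldsymbol\epsilon,
\qquad
\mathbf V = \widehat\Sigma_g \otimes \mathbf G +
            \widehat\Sigma_\epsilon \otimes \mathbf I,
\]
with phenotypes and dosages mean-centred (the model carries no intercept).
\(\widehat{\mathbf s}_j = (X'V^{-1}X)^{-1}X'V^{-1}\mathbf y\) estimates all
\(t\) effects jointly; standard errors come from \((X'V^{-1}X)^{-1}\) with
\(\mathbf V\) treated as known, and p-values are two-sided Wald tests. In
the eigenbasis of \(\mathbf G\), \(\mathbf V\) is block diagonal
(\(d_i\Sigma_g + \Sigma_\epsilon\)), so after a one-off \(O(n^3)\) setup the
whole scan is three matrix products plus \(m\) tiny \(t \times t\) solves —
\(O(n t^2)\) per SNP. Monomorphic SNPs are skipped with a warning; raw
p-values are reported (no genome-wide threshold is imposed) and `rank_top_snps`
orders SNPs per trait with coordinate tie-breaks.

## SEM-GWAS

Given the learned DAG, the recursive structural system is
\[
\mathbf y = \boldsymbol\Lambda \mathbf y + \mathbf w s + \mathbf Z\mathbf g
 + \boldsymbol\epsilon,
\]
with \(\boldsymbol\Lambda\) strictly lower triangular under a topological
trait ordering (ties broken lexicographically for a reproducible layout).
Two identification/estimation choices are deliberate and stated:

* **Diagonal structural-residual covariance.** Required for identification
  of a fully recursive system; under it, per-equation estimation is full
  information. Each equation is fitted by GLS with its own single-trait
  plug-in covariance \(V_i = \widehat\sigma^2_{g,i}\mathbf G +
  \widehat\sigma^2_{\epsilon,i}\mathbf I\).
* **Two-stage \(\Lambda\).** Structural coefficients are estimated once,
  without SNPs; per-SNP direct effects then come from each trait's equation
  with the SNP and the parent traits fitted jointly (not sequentially
  residualised, avoiding correlated-regressor bias).

The decomposition is then bookkeeping: the indirect effect along a directed
path \((k \to \dots \to i)\) is the product of the \(\lambda\)s on the path
times the direct effect on \(k\); the total effect on \(i\) is the direct
effect plus the sum over all incoming paths, and equals row \(i\) of
\((\mathbf I - \boldsymbol\Lambda)^{-1}\) applied to the direct-effect
vector — an identity the test suite checks to \(10^{-12}\) over \(10^5\)
random systems. Parentless traits have total = direct by construction.

With \(\boldsymbol\Lambda = 0\) the structural model collapses to MTM-GWAS.
Note one numerical subtlety: SEM direct effects are per-equation GLS while
MTM-GWAS is a joint multivariate GLS, so with an empty DAG the two coincide
*exactly* only when the plug-in covariance matrices are diagonal; with
correlated components they agree in expectation but not digit-for-digit.

# The synthetic world

`sim_scenario()`/`simulate_traits()` generate data with known architecture:

* Genotypes: \(p_j \sim U(\text{maf range})\), dosages
  \(\mathrm{Bin}(2, p_j)\) i.i.d. — Hardy–Weinberg, **no LD, no population
  structure** (both are out of scope for the generator).
* Structural-residual traits \(u_i = g_i + q_i + e_i\): polygenic \(g\)
  drawn through the realized GRM with a chosen cross-trait correlation,
  optional sparse QTL \(q\), and noise scaled so
  \(\mathrm{var}(g+q)/\mathrm{var}(u)\) matches the target heritability.
  `u_var` sets the residual-trait variance (0 = deterministic node).
* Observed traits propagate through the DAG in topological order,
  \(y_i = \sum_k \lambda_{ik} y_k + u_i\).

The four-trait preset (`rice_like_scenario()`) encodes a diversity-panel
shaped dataset: n = 341, m = 10,000, traits PSA/RB/WU/WUE,
\(\lambda\) = 0.761 (PSA→WU), 0.963 (PSA→WUE), 0.045 (RB→WUE), and
structural-residual heritabilities (0.677, 0.733, 0.643, 0.576). The preset
uses an *identity* polygenic correlation for the structural residuals: the
strong observed genetic correlations (e.g. PSA–WUE) then arise from
propagation through \(\Lambda\), which is exactly the data-generating story
a recursive SEM with diagonal residual covariance can identify. Stated
heritabilities apply to the residual traits *before* propagation, so
realized downstream heritabilities differ slightly — a documented
consequence, not a calibration target.

## What a green test does and does not establish

The generator's unstructured panel is deliberately the hardest case for
variance-component identification: with i.i.d. markers the GRM is close to
the identity (eigenvalue spread \(\approx \sqrt{n/m}\)), so h² and the split
of trait covariance into \(\Sigma_g\) versus \(\Sigma_\epsilon\) are weakly
identified at n ≈ 200–341. Consequences we have measured and accept:

* The posterior mean h² and a REML grid-search estimate of the *same* data
  can differ substantially when the restricted likelihood is nearly flat
  (REML drifts to a boundary; the posterior stays interior). On a
  family-structured GRM the two agree to < 0.03 — the samplers are right,
  the unstructured world is just uninformative. The single-dataset sanity
  criterion therefore passes or fails with the seed.
* Posterior-mean genetic values are shrunken trait mixtures; structure
  learning on them recovers the two strong arcs reliably, the 0.045 arc
  rarely — hence the "2 of 3 arcs" acceptance bar.

Real diversity panels carry relatedness and LD that make all of these
quantities much better identified; a green suite validates correctness of
the machinery and calibration of the tests, not field performance.

# Numerical choices

* GRM jitter: \(10^{-6}\cdot\overline{\mathrm{diag}}\) when
  \(\lambda_{\min} < 10^{-8}\lambda_{\max}\).
* QC keeps SNPs with call rate strictly > 0.95 and MAF strictly > 0.05
  (the removal rule read literally); allele frequencies are recomputed on
  the analyzed panel before centering (an external reference is not
  available), and after mean imputation the frequencies are unchanged by
  construction.
* Mean imputation (missing → \(2p_j\)) substitutes for haplotype-based
  imputation, which is out of scope.
* Node score floors the ML variance at `1e-300` so exact-copy parents give
  a large finite score instead of overflow.
* Hill-climbing accepts a move only if the gain exceeds `1e-10`
  (strict improvement against float noise); direction ties at exactly 0.5
  in model averaging resolve lexicographically.
* Wald z-tests treat the plug-in covariance as known — the definition of
  the reported p-values; under the null simulation their type-I error is
  within [0.035, 0.065] at \(\alpha = 0.05\) and genomic control is within
  [0.9, 1.1].

# Known limitations

* Two-stage plug-in components ignore their own estimation error; SEs are
  slightly optimistic for the variance-component-driven part (p-value
  calibration is nevertheless verified empirically).
* Per-equation SEM variance uses the observed-trait components for
  children, overstating the conditional residual variance — conservative
  for direct-effect SEs, irrelevant for the point estimates.
* No cyclic/simultaneous systems, no latent-factor SEM, no
  population-structure covariates beyond the GRM, no LD-aware candidate-gene
  logic beyond a fixed ±200 kb window.
* The bootstrap counts an edge's presence over hill-climbing replicates;
  with fewer than ~100 replicates the strengths themselves are noisy.
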