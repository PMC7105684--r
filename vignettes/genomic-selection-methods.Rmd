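---
title: "Two-stage genomic selection with spatial field-trial adjustment: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage genomic selection with spatial field-trial adjustment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsbreed)
```

gsbreed analyses multi-cycle, multi-environment breeding trials of
outcrossing perennials in which every genet (a unique, heterozygous
individual) is grown once, as a single plant on a field grid, and
genotyped by sequencing. The package covers the full path from raw
genotype calls to training-set design: GBS call filtering, naive
imputation, the realized additive genomic relationship matrix (GRM),
stage-1 spatial mixed models, stage-2 GBLUP, and cross-validation /
transferability evaluation. A seeded breeding-program simulator with
complete ground truth backs every stage with parameter-recovery tests.

## The two-stage model

Phenotypes from each breeding cycle and trait-year are first adjusted
per cycle with the mixed model

$$y = Xb + Zu + e, \qquad u \sim N(0, \sigma^2_A K),$$

where $X$ carries an intercept (plus a fixed site effect when a cycle is
split over two fields), $Z$ maps plot observations to genets, and $K$ is
the VanRaden GRM computed from all genotyped material. Each site has its
own residual structure built from separable first-order autoregressive
correlation along rows and columns of the planting grid,
$\Sigma_c(\rho_c) \otimes \Sigma_r(\rho_r)$, the standard model for
smooth fertility and moisture trends in unreplicated field nurseries.

Two residual parameterisations are available in `stage1_control()`:

* `nugget = TRUE` (default): the site residual is
  $\sigma^2_{e}\,[\phi\, \Sigma_c \otimes \Sigma_r + (1-\phi) I]$, a
  spatially structured share $\phi$ plus independent plot noise. Single
  plants measured once always carry measurement error that is not
  spatially smooth; omitting the independent term forces that error
  into whichever other component can absorb it.
* `nugget = FALSE`: the pure separable residual
  $\sigma^2_e\, \Sigma_c \otimes \Sigma_r$. This is the classical
  row-column AR1×AR1 formulation and is the configuration checked
  against dense likelihood-grid oracles in the test suite.

Gaps in the grid are handled by indexing the correlation matrix at the
observed plots only — no phantom-plot augmentation. This is an
approximation to full separable-residual software behaviour, exact for
the correlation structure among observed plots.

Stage 2 fits GBLUP on the per-genet stage-1 outputs,

$$y = 1\mu + g + e, \qquad g \sim N(0, K\sigma^2_g),$$

yielding genomic estimated breeding values (GEBVs) for *every* genet in
$K$, phenotyped or not, and the genomic heritability
$h^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_e)$.

### Which stage-1 output feeds stage 2

`extract_blups()` returns three per-genet columns, and the choice
matters:

* `blup` — the genomic BLUP $\hat u$. Faithful to the classical
  two-step description, but already smoothed by $K$: a second-stage
  variance-component fit on $\hat u$ is structurally driven toward
  $h^2 \approx 1$ because $\hat u$ lies in the span of $K$ by
  construction.
* `value_adj` (default prediction response) — phenotype minus fixed
  effects minus the *fitted spatial field*. Spatial trend is removed
  without smoothing the genet-level signal, which is what a prediction
  response needs.
* `value_raw` — phenotype minus fixed effects only. Free of any BLUP
  shrinkage, so second-stage REML on it recovers phenotype-scale
  variance components. The pipeline reports heritability from this
  response; recovery of simulated $h^2 \in \{0.3, 0.6\}$ at $n = 600$
  genets, $m = 2000$ markers is part of the acceptance suite (tolerance
  $\pm 0.1$ on the median of 10 simulations).

Prediction-ability rankings are essentially unaffected by this choice
(Pearson correlation is invariant to the monotone part of shrinkage);
the heritability estimate is strongly affected, which is why the two
uses get different defaults.

## REML machinery

Stage 1 profiles the overall residual scale out of the restricted
likelihood in closed form and searches the remaining parameters
($\mathrm{atanh}\,\rho$, $\mathrm{logit}\,\phi$, log variance ratios)
by Nelder–Mead, initialised from lag-1 autocorrelations of OLS
residuals along grid rows and columns. A dense Cholesky factorisation
per evaluation, with cached integer plot-distance matrices and
power-table AR1 construction, keeps one evaluation at roughly 25 ms for
600 plots. Convergence is declared on relative log-likelihood change
(`reltol`, default 1e-9, at most `maxit = 500` evaluations). The fitted
optimum is validated in the tests against brute-force likelihood grids
(agreement within 0.5 log-likelihood units on 25-plot toys) and against
an independent one-way REML implementation (lme4) in the
$\rho = 0$, $K = I$ special case.

Stage 2 exploits the two-component structure: after projecting out the
intercept, one eigen-decomposition of $K_{\text{train}}$ turns the REML
problem into a one-dimensional profile over
$\lambda = \sigma^2_g/\sigma^2_e$, solved by golden-section search on
$\log\lambda \in [-14, 14]$. This is exact, deterministic and fast
enough to refit inside every cross-validation fold. Ratios pinned at
the lower search boundary are reported as $\sigma^2_g = 0$.

Numerical safeguards: relationship matrices are bent to positive
semi-definiteness when their smallest eigenvalue falls below $10^{-6}$
(ridge by default, eigenvalue flooring by option); autocorrelations are
capped at $|\rho| \le 0.98$; failed Cholesky factorisations during the
search simply mark a parameter point as infeasible.

## Genotype filtering

`apply_filters()` runs a fixed order: depth rules → marker filters →
genet filter → one final marker-statistics recomputation. Defaults
follow standard GBS curation for heterozygous outcrossers:

| rule | default | boundary |
|---|---|---|
| homozygote minimum depth | 4 reads | `< 4` set missing |
| heterozygote contrasting reads | 2 per allele | `< 2` of either allele set missing |
| minor allele frequency | 0.01 | strictly greater than |
| marker call rate | 0.30 | inclusive (≥) |
| genet missingness | 0.95 | strictly more than → removed |
| PCA subset (MAF, call rate) | 0.05 / 0.50 | both strict |

The boundary semantics (strict vs inclusive) follow the phrasing of the
rules they implement and are pinned by unit tests. Missing calls after
filtering are imputed naively — marker-mean dosage $2p_k$ or
Hardy–Weinberg draws from Binomial$(2, p_k)$ — a documented stand-in
for haplotype-phasing imputation: GRM construction is dominated by
common variants, for which mean imputation is standard and adequate
(the degrade→filter→impute round trip preserves GRM off-diagonals with
correlation ≥ 0.95 at mean read depth 8 in the tests).

## Relationship matrix

$K = \theta M_c M_c'$ with columns centred at $2p_k$ and
$\theta = 1/(2\sum_k p_k(1-p_k))$ — the VanRaden normalisation, which
the cited A.mat methodology pins down even though $\theta$ is otherwise
just "a proportionality constant". Allele frequencies come from the
current filtered, imputed data set (matching A.mat's default), not from
founders. Monomorphic markers are excluded from both the cross-product
and the normaliser. One global $K$ is built from all genets and then
subset per analysis; building per-cycle matrices would change allele
frequencies cycle by cycle and make GEBVs incomparable across training
designs.

## Evaluation schemes

* **Within-cycle CV**: genets split into 5 folds (random partition,
  sampling without replacement), each fold predicted from the other
  80%; repeated (default 100×); per repetition the five folds' held-out
  predictions are pooled before correlating. Pooling per repetition was
  chosen over per-fold correlation for stability at small cycle sizes;
  `pool = "fold"` restores the alternative. Sibling leakage between
  folds is deliberately allowed — it matches how these training sets
  are used in practice.
* **Across-cycle**: train on one cycle, predict all others; a predicted
  cycle equal to the training cycle falls back to within-cycle CV and
  is flagged.
* **Leave-one-cycle-out**: train on the union of all other cycles.
* **PCA-similarity and program subsets**: training restricted to one
  side of a principal-component split (default: component 2 at score 0
  — the natural dividing line of a centred PCA; both configurable) or
  to one breeding program's material.

Prediction ability is the Pearson correlation between GEBVs and the
held-out genets' adjusted values, with Fisher-z 95% confidence
intervals ($\mathrm{atanh}$, half-width $1.96/\sqrt{n-3}$).
`best_model()` labels a candidate training design better/worse than the
leave-one-out reference only when the 95% CIs do not overlap; no
multiple-testing correction is applied, matching the CI-overlap
procedure it implements. Eligibility gates — at least 100 training
genets, at least 350 stage-1 observations per cycle-trait — are
enforced with explicit override flags, and ineligible combinations are
reported as such rather than dropped silently.

## The simulator

`sim_config()` → `simulate_breeding_program()` emulates the study
system end to end: founders drawn at Hardy–Weinberg equilibrium with
allele frequencies uniform on (0.05, 0.95); truncation selection of the
top fraction each generation on a phenotype with the configured
heritability; Mendelian gamete sampling at unlinked biallelic markers;
per-cycle evaluation at a cycle-specific site; G×E as a between-site
genetic correlation on additive effects (compound symmetry), rather
than explicit QTL×E effects — sufficient to generate the
within-vs-across-environment prediction gap with one parameter; plot
error as an AR1×AR1 random field plus independent noise, scaled so the
realized single-site heritability matches its target; and GBS-style
degradation in which per-call depth is Poisson, reads sample the two
parental alleles, zero-depth calls are missing and heterozygotes
collapse to homozygous calls when all reads hit one allele — exactly
the error mode the depth filters exist to catch.

Two architecture presets encode the contrast between trait classes:
`"domestication"` (10 QTL, cross-site genetic correlation 0.9, target
$h^2$ 0.7 — shattering/threshing-like traits) and `"agronomic"` (500
QTL, correlation 0.3, target $h^2$ 0.4 — yield-like traits). Default
scale parameters (48 founders, 600 genets/cycle, 2000 markers, 20%
selected, mean depth 8, spatial variance share 0.2, $\rho = 0.4$) are
desk-scale stand-ins for a programme of thousands of genets and tens of
thousands of SNPs; they were chosen once as realistic values for GBS
breeding nurseries and are not tuned per analysis.

What the simulator does **not** model: linkage maps and real
chromosome structure (markers are unlinked by default; the package is
used on an allohexaploid treated as diploid-dosage data), dominance and
epistasis, selection-index updating within a cycle, and
depth-dependent allele-specific bias. Passing recovery tests on this
generator therefore demonstrates correctness of the estimation
machinery under the stated generative model, not robustness to, e.g.,
strong linkage disequilibrium structure or non-additive inheritance.

## Problem sizes used by the automated checks

The test and acceptance suites run entirely on simulated data at sizes
chosen to finish on a single CPU while keeping estimates stable:
GRM oracle checks at 50×200; GBLUP–ridge equivalence at $n$=100,
$m$=500; likelihood-grid comparisons at $n \le 30$; heritability
recovery at $n$=600, $m$=2000 (5 simulations per level);
autocorrelation recovery on 20×20 grids (20 replicates per truth value,
$h^2$ 0.3, spatial share 0.6 — conditions with enough spatial signal
for the parameters to be well identified); transferability contrast at
2 cycles × 300 genets × 1000 markers (20 worlds per preset). The
pipeline determinism check reruns a 3-cycle, 110-genet programme and
compares output tables byte for byte.

## Known limitations

* Stage-1 fits with weak spatial signal (small spatial share or low
  $h^2$) sit on a likelihood ridge between "low $\rho$, no nugget" and
  "higher $\rho$ plus nugget"; estimates of $\rho$ are then honest REML
  optima but individually noisy. Medians across replicates are stable.
* The heritability reported for a trait-year is a single-site genomic
  heritability; it is not decomposed into G×E components.
* Variance-component standard errors are not reported; inference on
  prediction ability goes through Fisher CIs on correlations instead.
* The two-site stage-1 model estimates separate residual parameters per
  site but a single genetic variance; site-specific genetic variances
  are out of scope.
* HapMap input supports the common diploid two-letter and IUPAC
  single-letter codings only.
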