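---
title: "Methods: dual-track consensus differential expression for small multimodal cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-track consensus differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`abseqde` analyses targeted multimodal single-cell panels (a few hundred
RNA features plus a few dozen antibody-derived surface-protein tags
measured in the same cells) on small clinical cohorts. This vignette is
the package's own account of the statistical machinery: the models, the
parameters that matter, the numerical choices, what the bundled simulator
does and does not emulate, and the known limitations.

## The estimation problem

With ~50,000 cells but only 14 subjects, the effective sample size for any
between-subject comparison is 14, not 50,000. Cells within a subject are
correlated (shared genetics, disease state, processing), so treating them
as independent wildly overstates evidence; collapsing to one value per
subject respects the design but discards the cell-level resolution and is
underpowered at this n. The package therefore runs two tracks and requires
them to agree.

## Per-cell track: NB mixed model

For one feature within one annotated cell type, counts $y_{ij}$ (cell $i$,
subject $j$) follow

$$y_{ij} \mid u_j \sim \mathrm{NB}(\mu_{ij}, \phi), \qquad
\log \mu_{ij} = \beta_0 + \beta_x x_j + \gamma^\top c_j + o_{ij} + u_j,
\qquad u_j \sim N(0, \sigma^2),$$

with $\mathrm{Var}(y \mid u) = \mu + \phi \mu^2$. Here $x_j$ is the binary
outcome of interest, $c_j$ the covariates — processing batch and the other
outcome; the two outcomes swap roles between the two contrasts — and
$o_{ij} = \log N_{ij}$ the log total count of cell $i$ over the tested
modality's panel. The offset uses the panel total of the *same modality*
only: surface-tag counts are ~30× deeper than the targeted RNA counts and
would otherwise dominate the size factor.

Key parameters and defaults:

* `nodes = 10` — Gauss–Hermite quadrature nodes per subject integral.
  Results are insensitive to this (doubling to 20 moves coefficients by
  < 1e-4 on simulated data; asserted in the test suite).
* `min_cells = 20`, `min_expressing = 3` — a (feature, cell type) is only
  testable with at least 20 cells in the cell type, both outcome groups
  represented by ≥ 2 subjects, and ≥ 3 expressing cells. Untestable
  combinations are reported with a machine-readable reason rather than
  silently dropped, so the two tracks stay aligned row-for-row.
* One dispersion $\phi$ per (feature, cell type), jointly maximized with
  $\beta$ and $\sigma^2$. All subject-level extra-variance is housed in
  $\sigma^2$; with 14 subjects a separate subject-level dispersion is not
  identifiable.
* Wald tests on $\beta_x$, BH-adjusted across the full declared family:
  all features × cell types × both contrasts, with RNA and protein
  adjusted as separate families (they are separate panels with very
  different depths and are reported as separate analyses).

### Numerical choices

The marginal likelihood factorizes over subjects; each subject's
one-dimensional integral is evaluated by adaptive Gauss–Hermite
quadrature: a damped Newton search finds the conditional mode of $u_j$
(the integrand is log-concave, so this is globally stable), the local
curvature rescales the nodes, and the node sum is accumulated in log space.
Two implementation details matter for speed and are worth recording. The
NB log-density splits into a node-independent part (all gamma-function
terms, cached over the distinct count values, which are few in sparse
panels) and a node-dependent part that costs a single `log1p` per
(cell, node). And the per-subject modes are warm-started across likelihood
evaluations.

The optimizer is bounded quasi-Newton (`nlminb`) over
$(\beta, \sigma, \sqrt{\phi})$, initialized deterministically from a
Poisson GLM fit, with relative tolerance `1e-6` and 200 iterations. The
variance components are parametrized on their *natural* scale with a lower
bound of zero rather than on the log scale: for features whose data carry
no subject heterogeneity (or no overdispersion) the log-scale optimum sits
at $-\infty$ and a quasi-Newton crawl toward it costs hundreds of
iterations, whereas on the natural scale the optimizer terminates cleanly
at the bound. A `boundary` flag records $\hat\sigma^2 = 0$ solutions. At
that boundary the quadrature degenerates exactly to the NB GLM likelihood,
which is also how the fit is validated: on data simulated with
$\sigma^2 = 0$ the coefficients agree with an independently fitted
`MASS::glm.nb` to better than 1e-3 (1e-4 at tightened tolerance).

Wald standard errors come from the numerically differentiated Hessian of
the negative log-likelihood at the optimum; when a variance component sits
on its boundary the full Hessian is singular in that direction and the
$\beta$-block Hessian (variance parameters held at their estimates) is
used instead.

## Subject-level track: pseudobulk OLS

Counts are summed over all cells of each (subject, cell type) unit; units
with fewer than `min_cells = 3` cells are excluded and listed. Normalized
expression is $\log_2(\mathrm{CPM} + 1)$ with counts-per-million computed
within each modality's panel. Each feature is fit by OLS on the same
design (outcome + batch + other outcome), one observation per unit, with
two-sided t-tests for the outcome coefficient. No multiplicity adjustment
is applied on this track: the consensus rule consumes the raw p < 0.05 as
a confirmation, not as a discovery criterion.

The reported pseudobulk `effect` is converted from the fitted log2 scale
to natural log ($\times \ln 2$) so both tracks and the simulator's ground
truth share units. Note that a log-transformed-CPM group difference is a
biased estimator of the NB log-fold change when counts are shallow (the
concavity of the log depresses the noisier, lower-expression group more);
at the simulator's default depths the bias is ~0.1 on effects of 1 and the
track recovers unit effects within ±0.2, which the test suite asserts.

## The consensus rule

A feature is declared differential in a cell type and contrast when all
three hold: (1) mixed-track q < 0.05, (2) pseudobulk p < 0.05, and
(3) both tracks' effect estimates agree in sign (strict: a zero effect
fails). Entries untestable in either track are never called. The called
set is therefore a subset of the mixed-track FDR set — an invariant the
suite asserts on every simulation.

Why this design: per-cell mixed models with 14 subjects are
anti-conservative. On the simulator's study-like configuration
($\sigma = 0.5$, 14 subjects) the mixed track's null rejection rate at
nominal 0.05 is ~0.15 — the classic few-cluster Wald inflation — and its
realized FDR at q < 0.05 is well above 5%. The pseudobulk confirmation and
direction check prune exactly the calls that the subject-level evidence
does not support; on recovery simulations the consensus set's empirical
FDR is consistently below the mixed track's, at a small sensitivity cost
(≥ 0.8 for natural-log fold changes of 1.5 is asserted). Conversely, the
mixed track's Wald machinery itself is calibrated: with a fully null
generator (no effects, no subject heterogeneity, no batch effects) the
p-values are uniform and the rejection rate at 0.05 lies in [0.03, 0.07]
over ~1000 feature-tests.

## Cell-type composition

Per-subject cell-type proportions are tested per cell type and contrast by
OLS on logit-transformed proportions with the same covariate structure.
Zeros are handled by count-based smoothing before the transform,
$p^* = (k + \varepsilon)/(n + 2\varepsilon)$ with $\varepsilon = 0.5$
(a Haldane–Anscombe-style pseudo-count), which keeps the logit argument
strictly inside $(0,1)$ and leaves balanced counts exactly at logit 0.
Each cell type is transformed and tested independently (no joint
compositional model — see Limitations); BH runs across all cell types ×
both contrasts as one family, separate from the expression families.

## Confounder robustness

Because n = 14 cannot support joint adjustment, each eligible clinical
factor is appended to the mixed-model fixed effects *one at a time*, and
the signed $-\log_{10} p$ vectors with and without the factor are
correlated (Pearson by default; Spearman available) across all features,
per cell type and pooled. Eligibility requires adequate variation: after
binarizing a multi-level factor as majority level vs rest, the minority
category must hold at least `min_minority = 4` subjects ("more than 3").
The threshold is exposed because two clinically interesting factors in the
packaged cohort (donor source, acute GvHD) sit exactly at a minority of 3;
with `min_minority = 4` they are excluded by the rule as stated.
Multi-level factors are binarized because a 14-subject design cannot
estimate multi-level effects. Cell types whose augmented design is
singular (factor aliased with an existing covariate) are skipped with a
warning. On simulations where the added factor has no true effect, the
correlation exceeds 0.9 for ≥ 90% of cell-type fits — the behaviour a
robust prioritization should show.

## Geneset enrichment

Consensus-called RNA features per (cell type, contrast) are tested for
over-representation in GMT genesets with the one-sided Fisher exact test
(hypergeometric upper tail). The background is the *measured panel*, not
the genome: a targeted panel is itself a strong selection, and
genome-background enrichment would mostly rediscover the panel design.
Genesets are intersected with the panel on load; no multiplicity
adjustment is applied — with a few hundred genes the test is deliberately
reported at a nominal 0.05 highlight threshold.

## The simulator

`sim_config()` defaults emulate the motivating study design: 14 subjects
in 3 processing batches with joint outcome counts 1/5/4/4, 15 cell types,
397 RNA + 41 protein features, and 2,500–4,700 cells per subject (~50,000
total). Counts are NB draws with log-mean = feature baseline + per-(cell
type, feature) offset + per-(batch, feature) effect + outcome effect +
per-(subject, feature) random intercept + log size factor:

* baselines are log-normal, protein baselines ~30× higher (ADT-like);
* $\sigma_{\text{subject}} = 0.5$, $\phi = 0.4$, batch SD 0.2 — magnitudes
  typical of targeted single-cell panels;
* per cell type and contrast, 10% of features carry a true effect of
  random sign with magnitude ~ $N(1.5, 0.25)$ natural-log units;
* cell size factors are log-normal (SD 0.3) so the offset term is
  non-trivial;
* cell-type proportions are geometrically decreasing, Dirichlet-perturbed
  per subject with concentration 150 (between-subject logit SD ≈ 0.2 per
  type). The concentration was set so that the generator's prescribed
  composition calibration holds at the study design: a +1 logit shift on
  one cell type is detectable at q < 0.05 in ≥ 80% of replicates, while
  null generators yield essentially none;
* a configurable fraction of cells is emitted as debris-like QC failures
  (size factor ×0.01, driving RNA totals far below the 50-UMI floor) and
  as flagged multiplets (size factor ×2);
* one shared subject intercept per (subject, feature) rather than one per
  cell type — the simplest structure consistent with the downstream model,
  which is fit per cell type anyway.

Everything is reproducible from the config seed, and the ground-truth
record (true LFC sets, variance components, per-cell QC labels) makes
every downstream stage testable.

What the generator does **not** emulate: UMI/barcode chemistry and error,
ambient RNA, feature–feature correlation beyond the shared subject and
batch factors, cell-type-specific subject effects, mean–dispersion trends,
or annotation error in the cell-type labels (labels are consumed as given
throughout the package — clustering and annotation are out of scope).
Passing tests therefore demonstrate that the statistical machinery does
what it claims under a correctly specified NB world; they do not certify
behaviour under annotation error or strong cross-feature dependence.

## QC

Cells are removed when flagged as multiplets or when total RNA UMI < 50,
detected RNA genes < 35, or novelty < 0.55, each cell attributed to the
first matching filter. Metrics use the RNA panel only — protein tags would
inflate the totals, and the thresholds only make sense for a ~400-gene
panel. The novelty score is implemented as
$\log_{10}(\text{genes})/\log_{10}(\text{UMI})$: the literal reading
"$\log_{10}(\text{genes per UMI})$" is non-positive for every real cell
(a gene needs at least one UMI), so a 0.55 threshold on it would remove
everything; the literal form remains available via
`novelty_method = "ratio"`. Filtering is idempotent and monotone in its
thresholds, both asserted property-style.

## Problem sizes used in validation

The simulator's default scale (~50,000 cells × 438 features × 15 cell
types) is the study condition, but the validation suites run the same
machinery on smaller instances chosen to keep the full test run in the
minutes range while leaving the per-fit problem realistically sized
(700–1,500 cells per mixed-model fit, 14 subjects throughout): null
calibration uses 250 features × 2 cell types × 2 contrasts (~1,000
feature-tests); effect recovery uses 120 features × 2 cell types at
160–220 cells per subject; composition and robustness suites use 5–30
features with study-sized cell loads. QC thresholds in small-panel test
fixtures are scaled to the panel (the 50/35 defaults assume ~400 genes).

## Known limitations

* Cell-type labels are trusted inputs; mislabeled or doublet-contaminated
  clusters propagate into every stage.
* The composition test treats cell types independently on the logit scale;
  proportions are compositional, so a large shift in one abundant type
  induces apparent shifts elsewhere. A Dirichlet-multinomial or ALR/CLR
  treatment is deliberately out of scope.
* The pseudobulk track's log-CPM effects are shrunken at low depth (see
  above); the consensus rule uses only their sign and p-value, and
  effect-size reporting should rely on the mixed track.
* With 14 subjects, robustness scans can only ever add one binarized
  factor at a time; they quantify sensitivity of the ranking, not
  deconfounded effects.
* The enrichment stage inherits the targeted panel: genesets are evaluated
  against a few hundred genes, so power is limited by design and results
  are reported at a nominal threshold.
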