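---
title: "Models and methods behind omegrow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind omegrow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

omegrow implements a complete desk-scale version of a multi-omics growth
modelling workflow for a bacterium: a normalized expression compendium, a
transcription-factor (TF) regression network, a metabolism-and-expression
(ME) model solved by bisection over linear-programming feasibility, a
machine-learning harness for growth-rate prediction, two-view ensembles,
and a loop that feeds model simulations into the learners and learned
targets back into the model.  This vignette explains the models, their
assumptions, the tunable parameters, and the design decisions taken where
the problem left the design open.  It states no empirical result beyond
what the package's tests and `scripts/acceptance.R` themselves compute.

## Compendium normalization

Raw sources are gene-by-array matrices on arbitrary positive scales with
explicit `NA` missing cells (never encoded as 0).  The pipeline applies
five stages in a fixed order: identifier harmonization, per-gene min–max
rescaling, order-of-magnitude outlier flagging, random-forest imputation,
and a final min–max rescaling.

Decisions taken where the procedure was underdetermined:

* **Scaling axis.** Min–max scaling is per gene across arrays.  Cross-
  condition profile comparisons require values that are comparable between
  genes, which per-gene scaling provides.  Constant rows map to 0 and are
  logged as degenerate.
* **Outlier rule.** "Orders of magnitude too large or too small" is made
  precise as $|\log_{10} x - \mathrm{median}_g(\log_{10} x)| > k$ with
  default $k = 2$ orders.  The test is evaluated on the original positive
  scale (before rescaling), because the log-magnitude criterion is
  meaningless on a [0, 1] scale; the flag is applied at its stage position
  in the pipeline.  The mask is monotone in $k$.
* **Imputation.** One pass of per-gene random-forest regression (default
  100 trees, `randomForest`): each gene with missing cells is regressed on
  all other genes over the arrays where it is observed, with remaining
  predictor gaps mean-filled.  Chained iteration was deliberately not used;
  a single pass keeps the imputation analyzable and deterministic per seed,
  and planted-relation tests show it recovers strong gene–gene
  relationships.
* **Differential expression.** Welch's two-sample t-test per gene on log2
  values with Benjamini–Hochberg adjustment; defaults `lfc_min = 1`,
  `alpha = 0.05`.  Group-label swapping exchanges the up and down calls
  exactly.

## TF–gene regression and edge confidence

Each target gene is regressed by ordinary least squares on the expression
of all its annotated regulator TFs across arrays.  Per-regulator
coefficients ($\beta$), standard errors and two-sided t-test p-values are
reported; **confidence is defined as $1 - p$**, and an edge with
confidence above 0.95 is classified activation ($\beta > 0$) or repression
($\beta < 0$).  No multiple-testing correction enters the headline
classification — per-edge confidence is reported raw, with BH-adjusted
p-values available in the same table.  Operon membership is carried as
annotation only: regression groups regressors per target gene, because the
reported quantities are TF-to-gene pairs.  Collinear regressors flag the
fit unstable and leave its edges unclassified.  Environmental covariates
are not included in the regression; the contract models TF expression
only.

## The ME model

### Coupling algebra

Reactions carry stoichiometric coefficients that are affine functions of
the growth rate $\mu$ (1/h), stored as (constant, $\mu$-linear) pairs:

| Coupling | Coefficient | Default rate |
|---|---|---|
| enzyme use by a catalyzed reaction | $-\mu / k_{\mathrm{eff}}$, $k_{\mathrm{eff}} = k_{cat} \cdot 3600$ | $k_{cat} = 65\,\mathrm{s^{-1}}$ fallback |
| ribosome use by translation | $-\mu L_{aa} / (k_{ribo} \cdot 3600)$ | $k_{ribo} = 12$ aa/s |
| RNA-polymerase use by transcription | $-\mu L_{nt} / (k_{rnap} \cdot 3600)$ | $k_{rnap} = 55$ nt/s |
| mRNA use by translation | $-(\mu + k_{deg}) / k_{\mathrm{eff},mRNA}$, $k_{\mathrm{eff},mRNA} = k_{ribo}\cdot 3600/L_{aa}$ | $k_{deg} = 8\,\mathrm{h^{-1}}$ |

All coefficients are affine in $\mu$ (the mRNA term expands to
$k_{deg}/k_{\mathrm{eff}} + \mu/k_{\mathrm{eff}}$), so no rational term is
needed in the serialization schema.  Transcription consumes one NTP per
template base (T read as U) and releases pyrophosphate; translation
consumes one charged tRNA per residue and 2 GTP-equivalents per residue
(elongation plus initiation).  tRNA charging is aggregated per amino acid
at this scale; per-codon records are supported structurally.  An
unmodeled-protein fraction (default 0.2) inflates the structural protein
demand of biomass.

### Solving

At fixed $\mu$ the model is a linear program.  Growth maximization is a
bisection on LP feasibility (default tolerance $10^{-6}$ 1/h): demands
increase with $\mu$, so feasibility is monotone, which the test suite
asserts on the toy models.  A quad-precision nonlinear solver is
unnecessary at this scale; instead the LP kernel (`lp_solve()`) is a dense
two-phase primal simplex with Bland's anti-cycling rule, explicit bound
rows, max-abs row equilibration, tableau refactorization every 40 pivots,
a scaled phase-1 feasibility threshold of $10^{-10}$, and a final
iterative-refinement solve of the basis system.  These choices keep the
mass-balance residual of reported solutions below $10^{-9}$.  With no
objective requested, solutions are parsimonious (minimum total flux),
which makes predicted expression well determined under degenerate
alternate optima such as parallel pathways (ties are then resolved
deterministically by the pivoting rule).

The substrate **shadow price** is the marginal growth gain per unit
uptake, computed as a forward-difference sensitivity
$\Delta \mu^* / \Delta u$ by re-running the bisection; in the batch region
the bisection path is unchanged by the bound and the difference is exactly
zero.  Growth-curve regions are labelled: SNL (strictly nutrient-limited)
where the shadow price exceeds $\varepsilon = 10^{-6}$ and the local slope
is within 5% of the initial slope; batch where the shadow price falls
below $\varepsilon$; Janusian in between.  Labels are made contiguous in
that order.

### The toy organism

`make_toy_organism()` generates the standard study organism: an rRNA gene
plus protein-coding ORFs for a structural biomass protein, a ribosomal
protein, an RNA polymerase subunit, and up to four enzymes over a small
glucose core (precursor branch, energy branch, a parallel precursor path
and a byproduct route).  ORFs are random valid coding sequences (ATG
start, sense codons, stop) of 90–300 nt.  Constants were fixed once, to
make the toy show the qualitative physiology the analyses probe, and are
recorded on the object:

* biomass consumes 10 precursor, 20 energy units and 0.3 protein units per
  unit growth — the hand-computable stoichiometric yield used as the test
  oracle follows directly from these numbers;
* enzymes are 12-subunit complexes with $k_{cat} = 0.3\,\mathrm{s^{-1}}$,
  which makes expression cost a visible (quadratic-in-$\mu$) part of the
  glucose budget and produces a curved Janusian transition;
* a bound on ribosome formation (the machinery ceiling) creates the batch
  plateau; switching it off removes the batch region within the standard
  uptake grid.  Even without the ceiling, growth remains intrinsically
  bounded by machinery autocatalysis (machinery must build machinery).

The RNA-to-protein mass ratio uses steady-state amounts from the
synthesis/dilution balance (mRNA diluted at $\mu + k_{deg}$, stable RNA
and protein at $\mu$) with average monomer masses (324 and 110 g/mol).
Transfer-RNA mass is not counted (charging is aggregated), so the ratio's
absolute level is lower than a cell's; its growth-rate dependence — the
quantity the tests assert — is unaffected.

## The machine-learning harness

Datasets are array-by-feature matrices with growth-rate labels and a view
tag (transcription or translation).  Splits are 80/20 and reproducible per
seed.  The four metrics are the coefficient of determination, root mean
square error, explained variance score, and mean absolute error, computed
from their defining formulas (the test suite pins a hand-computed example
and the RMSE ≥ MAE inequality).

**HDMPPK** runs six stages in acronym order: histogram gradient-boosted
importance ranking keeping the top $m = \min(200, p)$ features; DBSCAN
array-outlier removal; per-feature min–max scaling; PCA keeping 95% of
variance; binary particle-swarm search over component inclusion (30
particles, 50 iterations, inertia 0.72, cognitive and social weights
1.49) with 5-fold cross-validated 5-NN $R^2$ as fitness; and the final
fitness recorded.  None of those constants were given by the problem; they
are standard PSO settings.  The boosted ranking uses many shallow,
feature-subsampled rounds (depth 2, learning rate 0.05, column subsample
0.2, 500 rounds) so weak but real signal features accumulate importance —
a deliberate configuration choice for high-dimensional screening.  DBSCAN
is implemented in-package (no R implementation was available here) with
eps defaulting to the 0.9 quantile of 5-NN distances, and the removal is
skipped if it would drop more than half the arrays.  The report's selected
original features are those retained by the ranking stage; PCA/PSO select
derived components, which the report lists separately.

The sparse group lasso baseline is solved by proximal gradient descent
(soft-threshold then groupwise shrinkage, Lipschitz step size); $\lambda =
0$ keeps every feature and large $\lambda$ empties the model.

**Model families.**  k-NN regression (`FNN`), radial SVR (`e1071`), and
two small sequence models written in-package because no deep-learning
framework is available in this stack: a 1-D convolutional network (valid
convolution, ReLU, flattened dense output) and a single-layer LSTM over
`chunk`-sized steps of the feature vector, both trained full-batch with
Adam on standardized inputs, with hand-derived gradients, gradient-norm
clipping and per-seed deterministic initialization.  Feature vectors feed
the sequence models in column (genome-coordinate) order.  These nets are
sized for desk-scale data; on small sparse-linear benchmarks they are
honest but weak learners, which is why distribution-level checks of the
ensemble machinery use SVR members (see below) while the CNN/LSTM paths
are exercised by their own convergence, determinism and invariant tests.

**Optimizers.**  Grid (lattice sized to the budget), random, ant-colony
(16 discretization levels per continuous dimension, evaporation 0.1, 10
ants per generation), Harris-Hawks (population 10, standard
exploration/besiege updates with Lévy dives, clamped to the unit box), and
Bayesian optimization (Gaussian-process regression with an RBF kernel,
length scale $0.2\sqrt{d}$, expected-improvement acquisition over random
candidate draws).  All run in unit-cube coordinates decoded into typed
parameters, record every evaluation in a trace bounded by the budget, and
are deterministic per seed.  The scenario matrix pairs KNN with grid and
random search only, and SVR/CNN/LSTM with all five optimizers, per view:
17 scenarios per view, 34 in total.

## Ensembles

A two-view ensemble trains one member per view and combines them with an
ordinary-least-squares model (intercept plus two slopes) fitted strictly
on out-of-fold member predictions of the training arrays — no member sees
its own training targets at combination time, which a dedicated test
asserts by exploiting 1-NN's zero in-sample error.  The preset pairings
follow the field's labels (AB: optimized CNN on translation with optimized
LSTM on transcription; BB: LSTM twice; AA: CNN twice); the baseline is a
single SVR on the concatenated views.  Because single-split comparisons
are noisy, ranking claims are made on repeated rebuilds
(`compare_ensembles()`), mirroring the repeated-evaluation protocol.
Compendium profiles are scored by mapping genes onto each member's
training features, mean-imputing unmappable features (with a warning
count) and refusing to predict when more than half are unmappable.

## The integration loop

`generate_gemf()` simulates expression/growth arrays from the ME model
over a condition grid; `augment_dataset()` appends them to an experimental
dataset with origin flags, defaulting to a test-set extension, and leaves
the experimental rows byte-identical.  `update_me_model()` retunes the
model's expression modules toward target expression at a fixed growth
rate: each gene's translation-side mRNA demand is scaled by a bounded
multiplier (default bounds [0.2, 5]) under iterated proportional updates
(target/prediction ratio, clamped), with per-gene feasibility checks and
reverts.  No numerical scheme was prescribed for this step; proportional
fitting was chosen because the predicted expression responds monotonically
(indeed, near-linearly before renormalization) to the multiplier, so the
iteration decreases the squared deviation and — by construction — targets
equal to the model's own predictions are a fixed point with all
multipliers 1.  A gene's "correct" expression prediction is defined by a
band rule ($|pred - ref| \le 0.2$ on the normalized scale) with a tertile
rule selectable, since no correctness rule was stated for the headline
accuracy.

## Synthetic data and what passing tests show

Generators are deterministic per seed, always return the planted truth,
and write the corruption positions they used.  The expression generator is
a rank-5 latent-factor model on a log-normal positive scale with
condition-driven factor shifts, planted missing cells and magnitude
outliers placed exactly three orders from the gene median; it splits
output into two source tables with synonym identifiers so harmonization is
exercised.  Growth labels follow a sparse linear signal with a saturating
term, $y = S/(1 + S/\mu_{sat}) + \varepsilon$; regulatory truths plant
signed TF effects of magnitude 1–2 on a uniform TF background (a spread
wide enough that 500 arrays at noise 0.1 estimate each coefficient to a
few percent); the two-view benchmark gives each view an independent half
of the signal.

These generators emulate structure, not biology: real compendia have
correlated platform effects, non-random missingness, and regulatory
feedback that the latent-factor model does not produce.  Passing the
recovery tests therefore shows the algorithms are implemented correctly
and calibrated under their own assumptions, not that they would achieve
the same accuracy on laboratory data.

## Problem sizes

The test and acceptance workloads use: a 7-gene toy organism (~100
reactions), uptake grids of about a dozen points, regulatory recovery at
500 arrays and noise 0.1, the feature-selection benchmark at 400 arrays
with 20 informative among 500 features, the two-view benchmark at 240
arrays with 60 features per view, and 10-repeat evaluations where
distributional claims are made.  These sizes were chosen so every analysis
is exact enough to check against closed-form oracles while each stage
stays interactive.

## Known limitations

* The simplex kernel is dense and intended for desk-scale models; a
  genome-scale reconstruction would need a sparse LP solver and, for
  tightly coupled ME formulations, extended precision.
* The CNN/LSTM regressors are minimal single-layer architectures.
* tRNA mass is excluded from the RNA-to-protein ratio.
* The EM update tunes translation-side demand only; rRNA genes have no
  multiplier.
* Confidence calibration of the TF network assumes independent noise
  across arrays; autocorrelated condition series would inflate it.
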