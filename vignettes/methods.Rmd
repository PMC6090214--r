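---
title: "Methods: detection-limited expression, gene networks and explained survival variation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detection-limited expression, gene networks and explained survival variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

oatpnet implements a complete analysis path from raw RT-qPCR
quantification cycles to a penalized multivariable survival model with
network-structured predictors, in the setting of transporter-gene panels
in high-grade serous ovarian cancer. This vignette explains each model,
its assumptions, the tunable parameters, the numerical choices, and what
the synthetic cohort generator does and does not emulate.

## 1. Relative quantification with detection limits

Quantification cycles (Cq) are log2-scale measurements: one cycle is a
twofold difference in template. We normalize each gene against the
geometric mean of the reference genes' relative quantities, which on the
Cq scale is simply the arithmetic mean of their Cq values — this is the
numerically stable form and algebraically identical. With a per-gene
calibrator offset `calibrator_dcq` (ΔCq of the calibrator sample;
default 0, i.e. values relative to the reference mean only), the stored
value is −ΔΔCq, so larger means more expressed.

A Cq above the detection `threshold` (default 35 cycles, the
plateau beyond which amplification is not trusted) or a missing cell
marks the gene *undetectable* in that sample; the value is absent, not
zero. Genes detected in every sample are *complete*; the rest are
*detection-limited*.

**Assumption**: reference genes are detected in every sample. A sample
violating this cannot be normalized; the default is an error naming the
sample, with an opt-in `on_bad_reference = "drop"` that records the
exclusion in the preprocessing report.

## 2. Two-variable encoding of detection-limited genes

A detection-limited gene carries two kinds of information: *whether* it
is expressed above the limit and *how much*, given that it is. Each such
gene therefore contributes two model columns sharing one penalty group:

* the continuous log2 values, centered at the detected-value mean with
  undetected entries imputed at that mean (exactly 0 after centering, so
  the continuous coefficient is inert for undetected samples), scaled to
  unit variance;
* a 0/1 detection indicator, suffixed `_2K`.

Because the two columns share a group, every model selects or drops them
jointly. The mean-imputation choice makes the decomposition clean: the
indicator carries the full detection effect, the continuous column only
the dose effect among detected samples. A gene with fewer than 3
detected values cannot support a continuous coefficient and is an error
(such genes should be excluded up front); a gene declared limited but
detected everywhere is demoted to complete with a warning.

Clinical covariates — age in years, FIGO stage IV vs III, residual tumor
after debulking yes vs no — form a single group with penalty multiplier
0: they are established prognostic factors and are always carried,
never shrunk. Samples missing residual-tumor status are dropped from
modelling with a warning (cohort summaries keep them).

## 3. Two-part group comparison

Comparing a detection-limited gene between two groups with a rank test
on detected values alone discards the detection pattern; a proportion
test alone discards the dose information. The two-part statistic
combines both: a pooled two-proportion z on detection fractions
(z_B) and a Wilcoxon rank-sum on detected values (z_W), with
X² = z_B² + z_W² referred to χ² with 2 df. No continuity corrections
are applied anywhere, keeping X² = z² exact and the χ² reference clean.
Tests are two-sided throughout.

The continuous part uses the exact Wilcoxon null distribution when both
detected counts are ≤ 12 and there are no ties — important here because
the benign comparison group is small (n = 21 in the motivating design)
and the normal approximation is poor at such sizes — and otherwise the
normal approximation with tie correction. The working z_W is recovered
from the two-sided p with the sign of the rank-sum shift, so the
combination is consistent across branches.

Degenerate components are dropped: with no undetectables anywhere, or a
pooled detection fraction of 0 or 1, the point-mass part carries no
information; with fewer than 2 detected values in either group the
continuous part is unusable. The remaining component's own p is then
reported with 1 df; if both are degenerate the gene is untestable and
errors. Family-wise correction uses Benjamini–Hochberg across all tested
genes of the panel; genes undetected in both groups are excluded and
logged rather than tested.

## 4. Gene-graph selection

Partial correlations distinguish direct from indirect association: an
edge in a Gaussian graphical model is a nonzero partial correlation
given all other genes. Only complete genes enter (the Gaussian model has
no natural place for point masses), using tumor samples only.

Candidate graphs come from three families: a threshold grid on the edge
score min(|cor|, min over single-gene conditioning |pcor|)
(zero/first-order screening), per-node lasso neighborhoods over a
30-point penalty grid combined by the AND rule, and the same with
adaptive weights 1/(|ridge estimate| + 1e−6). The returned graph
minimizes the additive criterion

$$\mathrm{Crit}_K(G) = \sum_a \big[\, \mathrm{RSS}_a(ne_G(a)) + K\,|ne_G(a)|\log(p-1) \,\big],$$

the residual sum of squares of each node regressed on its neighbors
plus a per-neighbor penalty. K is the sparsity dial: because the penalty
is additive in the total neighborhood size, the selected edge count is
non-increasing in K over a fixed candidate set, which gives the K-sweep
its clean semantics. This explicit criterion was chosen over an
off-the-shelf graph selector precisely so that it is self-contained,
exactly reproducible, and provably monotone in K; its behavior under
independence is analyzable (a spurious edge needs a χ²₁ residual drop
exceeding K·log(p−1)).

Ties in the criterion break toward fewer edges, then the
lexicographically smallest edge set — selection is fully deterministic.
Node degrees are capped at `d_max = min(10, n − 3, p − 1)` so every
neighborhood regression is well posed. Connected components of size ≥ 2
become *networks*, summarized by the first principal component of their
standardized member columns (standardization, rather than raw scale,
keeps a highly variable member from dominating the score); the PC1 sign
is fixed by making the largest-magnitude loading positive. Genes in no
network stay as single features.

## 5. Grouped LASSO Cox and penalty selection

The model minimizes
$$\tfrac1n\,\ell_{\text{Breslow}}(\beta) + \lambda \sum_g m_g \sqrt{p_g}\, \lVert \beta_g \rVert_2 ,$$
where $\ell$ is the negative Breslow-tie log partial likelihood, $m_g$
the group multiplier (0 for clinical) and $\sqrt{p_g}$ the standard
group-lasso size weight. The group norm shrinks whole groups to exactly
zero, which is what keeps paired gene columns together. Solved by FISTA
(accelerated proximal gradient) with backtracking line search and the
group soft-threshold proximal step; iteration stops when the relative
objective change falls below 1e−9 *and* the Karush–Kuhn–Tucker residual
of the iterate is below 1e−7, so reported solutions verifiably satisfy
the optimality conditions (`kkt_residuals()` re-checks them). Columns
are standardized internally; coefficients are reported on the original
scale. Ties: Breslow inside the penalized objective (simple gradient),
Efron for unpenalized reporting fits via `survival::coxph`; the λ = 0
consistency check matches ties methods.

λ runs over 50 log-spaced points from λ_max (the smallest penalty
zeroing every penalized group, computed from group gradient norms at the
clinical-only fit; the top grid point sits a factor 1 + 1e−6 above it so
the all-zero solution there is numerically exact) down to 0.01·λ_max.
In-sample likelihood is trivially maximized at λ = 0, so "minimizing the
negative log likelihood" is read as *cross-validated* likelihood:
10-fold cross-validation stratified by event status, scoring each λ by
the Verweij–van Houwelingen partial-likelihood deviance (full-data minus
held-in log partial likelihood at the leave-fold-out estimate). The
final multivariable model is an unpenalized Cox refit on the clinical
block plus the selected groups, because hazard ratios, confidence
intervals and Wald p-values require an unpenalized information matrix;
paired genes report one Wald χ² on 2 df.

The same machinery with binomial deviance or squared-error loss gives
the grouped-lasso logistic/linear models used for signature association;
there the intercept is the unpenalized singleton.

## 6. Explained variation and its decomposition

The Schemper–Henderson predictive inaccuracy D is the weighted mean
absolute error of predicted survival status over the distinct event
times; subjects censored before an event time contribute their expected
error given survival to the censoring time, and times are weighted by
d_j / Ĝ(t_j⁻) with Ĝ the reversed-role Kaplan–Meier estimator of
censoring (left-continuous; at tied times events precede censorings;
times where Ĝ vanishes are dropped with a warning). The percentage of
explained variation is V = (D₀ − D_x)/D₀, with D₀ from the overall
Kaplan–Meier curve applied to every subject and D_x from the per-subject
Cox predictions S_i(t) = S₀(t)^{exp(η_i)} on the Breslow baseline.
Predictions are evaluated on the event-time grid only, which is where D
is defined.

Partial PEV of a factor is defined as refit-and-subtract: V(full) minus
V(full refitted without that factor's columns). A sequential
(order-dependent) decomposition was the alternative; refit-and-subtract
is order-free and deterministic, at the cost that partials need not sum
to the total — the decomposition is reported alongside the clinical-only
and total PEV rather than forced to add up.

K* is the sweep value maximizing V, smallest K on ties. One master seed
fixes the cross-validation folds across all K, so PEV differences
between K values reflect the graph structure, not fold noise.

## 7. Risk stratification

The final model's linear predictor is cut at its terciles
(linear-interpolation quantiles; ties at a cut stay together) into low,
medium and high risk. Group curves are means of member-subject
*model-predicted* survival functions — not Kaplan–Meier — which is why
they carry no censoring marks; the 5-year estimate is the curve value at
60 months (falling back to the last event time, with a warning, if the
horizon exceeds it). Confidence intervals are percentile bootstrap over
B = 200 resamples, refitting the unpenalized final model and re-deriving
tercile membership in each resample; selection (λ, K) is *not* repeated
inside the bootstrap, so the intervals are conditional on the selected
model, consistent with reporting conventions for post-selection refits.

## 8. The synthetic cohort generator

The generator emulates exactly the structure the analysis assumes, with
full ground truth: multivariate-normal log2 expression whose precision
matrix has unit diagonal and planted blocks; detection-limited genes
masked below fixed marginal quantiles (mirroring a Cq > 35 cut on the
latent scale); clinical covariates age ~ N(57, 10²) years, FIGO IV ~
Bernoulli(0.19), residual tumor ~ Bernoulli(0.29); survival from a
Weibull-baseline (shape 1.2, scale 60 months) Cox model over clinical,
gene, indicator and network effects; censoring as min(Uniform(0, c_max),
120 months) with c_max calibrated by root-finding so the expected event
fraction matches the target (default 0.61); and signature scores as
linear gene combinations plus Gaussian noise, with the binary subclass
from a logistic rule. All draws flow from one master seed through named
sub-streams, so enlarging one component never perturbs another.

Planted blocks are *chains*, not cliques: a block lists its members as a
path with precision off-diagonal −ρ on adjacent pairs, so every planted
edge has partial correlation exactly ρ and the matrix stays positive
definite. A clique parameterization cannot represent the default
block of four at ρ = 0.35 (positive definiteness caps pairwise partial
correlations of a k-clique at 1/(k−1)), and scaling it down would make
the planted structure unrecoverable at realistic sample sizes; the chain
design keeps the planted truth exactly on the scale the recovery checks
assume. The study-shaped fixture (`study_fixture`) adds a benign
comparison group drawn from the same covariance shifted down one log2
unit with unchanged detection thresholds — so benign samples show both
lower detected values and more non-detection, the pattern the two-part
test is built for.

What the generator does **not** emulate: amplification-efficiency
variation, plate/batch effects, non-Gaussian expression marginals,
informative censoring, correlation between clinical covariates and
expression, or real signature-score distributions. Passing tests
therefore demonstrate correctness of the statistical machinery under its
own assumptions, not robustness to the ways real cohorts violate them.

## 9. Numerical choices and test problem sizes

* Solver: FISTA with backtracking, restart on objective increase;
  convergence = relative objective change < 1e−9 plus KKT residual
  < 1e−7; warm starts along the λ path.
* Cox fits: `survival::coxph` with eps 1e−8-equivalent control and 100
  iterations; constant columns are rejected before fitting; monotone
  likelihood is surfaced as a non-convergence flag.
* Graph selection: deterministic tie-breaks (fewest edges, then
  lexicographic); degree cap min(10, n − 3, p − 1).
* Quartiles and terciles: linear interpolation (type 7), the most common
  convention; categorical percentages use non-missing denominators,
  event percentages the full cohort.
* Exact Wilcoxon branch only for tie-free samples with both sizes ≤ 12.

The test suite exercises the pipeline at cohort sizes chosen to match
the study design where it matters (n = 135 + 21 for the fixture; a
29-gene panel; K = 1–8; 10-fold cross-validation) and at n = 400 with
20–50 seeded replicates for recovery and coverage properties, which
keeps the full suite in the ten-minute range on one CPU while leaving
the planted effects comfortably detectable.

## 10. Known limitations

* PEV is computed on the same data used for network and variable
  selection and is therefore optimistic; an honest estimate would need
  nested resampling of the entire pipeline.
* The bootstrap intervals for 5-year survival are conditional on the
  selected model (see §7).
* The GGM stage assumes joint Gaussianity of complete genes; heavy tails
  or nonlinear dependence will distort both edge selection and PC1
  summaries.
* The two-part χ²₂ reference is asymptotic in the point-mass part;
  detection counts below ~5 per group make it approximate.
* Calibrator offsets are consumed as known constants; uncertainty in the
  calibrator is not propagated.
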