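---
title: "Fused network inference: models, penalties and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fused network inference: models, penalties and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusenet)
```

This vignette documents the statistical model `fusenet` implements, the
assumptions behind it, the tunable parameters and their defaults, and every
numerical convention a user reproducing or extending the results needs to
know.

## The dynamics-derived regression problem

Transcription is modeled linearly: the rate of change of gene *i*'s mRNA is
degradation at a shared rate $\alpha$ plus a weighted sum of regulator
levels,

$$\frac{d x_i}{dt} = -\alpha x_i + \sum_{j \ne i} \beta_{ij} x_j ,$$

with the sum over declared transcription factors and self-regulation
structurally excluded (the solver drops TF $j$ from the predictor set of
gene $j$; those coefficients are reported as exact zeros). The default
$\alpha = 0.1\,\mathrm{min}^{-1}$ corresponds to a 10-minute exponential
time constant for mRNA decay, a typical bacterial value; it is a single
shared scalar. Per-gene decay rates would slot naturally into
`build_response_design()` but are deliberately not estimated — with desk-
scale condition counts they are not identifiable jointly with the network.

`build_response_design()` discretizes this model: a time-series condition
pair $(t_k, t_{k+1})$ contributes the row
$(x(t_{k+1}) - x(t_k))/\Delta t + \alpha x(t_k)$ against the TF values at
$t_k$; a steady-state condition (derivative zero) contributes
$\alpha x(t_k)$ against the TF values at $t_k$. Time-series conditions
without a predecessor contribute nothing. $\alpha = 0$ is accepted only for
datasets with no steady-state conditions, because a steady row would then be
identically zero; the synthetic two-timepoint generator uses exactly this
convention.

**Standardization.** Predictor columns are centered and scaled to unit
variance under the *population* (1/n) convention, so a two-point column
$(1, 3)$ becomes $(-1, 1)$. All penalties operate on this scale; recorded
means and standard deviations let `rescale_network()` report coefficients
per original expression unit. The same 1/n convention is used for
$\mathrm{var}(\mathrm{TF}_j)$ in the confidence score, keeping the two
surfaces consistent. Constant columns are centered only and flagged.
Missing expression values are rejected at load — the model has no missing-
data mechanism and silent imputation would be worse than an error.

## Fused L2 estimation

Networks $\beta_S$ for all sources are estimated jointly by minimizing

$$\sum_S \|X_S\beta_S - Y_S\|^2 + \lambda_R\|\beta_S\|^2
  + \lambda_S \sum_{(g,k)\,\approx\,(h,l)} w\,(\beta_{g,k} - \beta_{h,l})^2 .$$

Constraints come from orthology (`constraints_from_orthology()`: one
constraint per regulator-ortholog pair crossed with each target-ortholog
pair; many-to-many orthologs expand to the full bipartite product) or from
operons (`constraints_from_operons()`: a TF's weights on two genes of one
operon are fused). Constraints are stored canonically (lexicographically
ordered endpoints) and deduplicated, and each carries a weight $w$ — the
hook adaptive fusion uses to modulate individual constraints.

The whole objective is a single least-squares problem after augmentation:
ridge rows $\sqrt{\lambda_R \kappa}$ on the coefficient diagonal and one
row per constraint with $+\sqrt{\lambda_S w}$ and $-\sqrt{\lambda_S w}$ at
the fused positions. The square roots matter: the squared residual of a
penalty row must reproduce $\lambda_S w (\beta_i - \beta_j)^2$ exactly, and
the tests verify the augmented normal equations against the ridge closed
form. $\kappa$ is 1 except on interactions listed in a prior network, where
it is `prior_relax` (default 0.1): prior-known edges are shrunk ten times
less, the mechanism used when half of a gold standard serves as priors.

Fusion couples response variables, but only within connected components of
the graph joining responses that share a constraint. `fusenet` decomposes
that graph (via `igraph`), solves each component's augmented system by a QR
factorization — never by forming normal equations — and batches all
unconstrained responses through the per-response ridge closed form. With
one-to-one orthology a component is one gene pair, roughly twice the
single-species system. Degenerate inputs: with $\lambda_R = 0$ a singular
component raises an error advising $\lambda_R > 0$ rather than returning
one of many minimizers.

**Iterative path solver.** For large many-to-many constraint blocks, and to
compute $\lambda_S$ paths cheaply, `solve_fused_iterative()` repeats
per-response ridge solves in which each fused coefficient is pulled toward
its partner's value from the previous sweep (parallel, Jacobi-style
updates, matching the iteration-indexed objective). Because the penalty
contributes $+\lambda_S w$ to both diagonals and $-\lambda_S w$ off
diagonal, the splitting converges whenever $\lambda_R > 0$; convergence
slows as $\lambda_S$ grows, which is why the direct solver remains the
default (`component_size_limit`, default 5000 coefficients, routes between
them). Cholesky factors are computed once per (response, $\lambda_S$) and
reused across sweeps; grid values are warm-started. The default tolerance
is $10^{-6}$ on the maximum coefficient change with `max_iter = 50`
(typical instances converge in about ten sweeps); hitting `max_iter` flags
the result and warns, never silently.

As $\lambda_S \to \infty$ with complete one-to-one fusion, the estimate
tends to the stacked-data ridge fit with the per-source penalties summed —
with identical coefficients enforced, the per-source Gaussian priors
multiply. The tests assert this limit at $\lambda_S = 10^8$, and also the
Gaussian-prior reading of the penalty: for two fused coefficients the
implied prior covariance matrix is the inverse of
$\lambda_R I + \lambda_S (\mathbf{1}_{gg} + \mathbf{1}_{hh} -
\mathbf{1}_{gh} - \mathbf{1}_{hg})$, giving variance
$(\lambda_R + \lambda_S)/(\lambda_R^2 + 2\lambda_R\lambda_S)$ and
covariance $\lambda_S/(\lambda_R^2 + 2\lambda_R\lambda_S)$ — $2/3$ and
$1/3$ at $\lambda_R = \lambda_S = 1$.

## Adaptive fusion

Orthology is an imperfect proxy for functional conservation: some
constraints are wrong, and a quadratic penalty forces even contradicted
pairs together. The saturating penalty keeps the quadratic behavior near
the origin but plateaus at a difference threshold $a$; beyond it the
derivative is zero and the pair is effectively *unfused*. The implemented
derivative is the unique continuous piecewise-linear function that is
$\lambda\theta$ near zero, tapers from $a/2$, and reaches zero at $a$:

$$p'(\theta) = \begin{cases}
\lambda\theta & \theta \le a/2\\
\lambda(a - \theta) & a/2 < \theta \le a\\
0 & \theta > a .
\end{cases}$$

(A penalty that is L1-like at the origin, as in SCAD or MCP, would assume
most *differences* are exactly zero; there is no reason to expect that, so
the origin stays quadratic.) The penalty value plateaus at
$\lambda a^2/4$.

The non-convex objective is minimized by iterated local quadratic
approximation: at each step every constraint's weight becomes
$p'(\theta)/(2\theta)$ at the current difference magnitude $\theta$ (limit
$\lambda/2$ at zero, exactly zero for $\theta \ge a$), and the resulting
convex fused-L2 problem is solved exactly. Since the weight is
non-increasing in $\theta$, each surrogate majorizes the true penalty and
the objective descends monotonically — asserted to $10^{-9}$ in the tests.
$\theta$ starts at zero for all constraints, so the first iterate is the
fully fused fit; with $\lambda = 2\lambda_S$ (the default scale matching)
adaptive fusion in the quadratic regime reproduces fused L2 at the user's
$\lambda_S$ exactly. $\theta$ is measured on the standardized coefficient
scale, the scale the solver operates on.

$a$ is not cross-validated (a 2-D grid over $(\lambda_S, a)$ would be
prohibitive and, more importantly, $a$ encodes a scientific hypothesis):
`select_a()` sets it to a percentile — default the 60th — of the absolute
differences between fused weights in *independently* fit networks, using
R's default linear-interpolation quantile. The percentile states the
working fraction of constraints presumed genuinely conserved; at the 60th,
roughly 40% of constraints start in the saturated zone. A constraint is
reported unfused when its final effective weight is zero. In the corrupted-
orthology simulations a substantial share of false constraints nonetheless
stays fused: sparse networks put many false constraints between near-zero
coefficients whose difference is small — such constraints are wrong but
harmless, and no difference-based criterion can (or needs to) detect them.

## Hyperparameter selection and the workflow

Selection is two-stage: $\lambda_R$ first by K-fold cross-validation with
$\lambda_S = 0$ (grid: 20 log-spaced values spanning
$10^{-3}\lambda_{\max}$ to $\lambda_{\max} = \max|X^\top Y|$), then
$\lambda_S$ along the warm-started iterative path at the chosen
$\lambda_R$ (default grid $\{0, 0.01, 0.1, 0.5, 1, 2, 5, 10\}$, which
includes the 1.0 operating point used throughout the comparative studies).
Held-out error is the mean squared prediction error pooled over sources;
ties break toward the larger penalty. The gold standard is never consulted
during selection. Folding is at the level of regression rows — each
steady-state condition or time-series transition is one atomic row; whether
whole time-series chains should stay together is a judgment call, and
row-level folding is the simplest defensible reading for the two-timepoint
designs used here.

`run_workflow()` orchestrates the full procedure: build constraints, split
each gold standard in half (seeded) into a prior half — used for TFA
estimation and ridge relaxation — and a leave-out half used only for
evaluation; then, for each outer fold, treat that fold's rows of the
evaluation source as *all* the available data (emulating the data-poor
regime), select penalties by nested CV, fit fused (or adaptive) and
independent models, rank edges, and evaluate precision–recall on the
leave-out half; finally average over folds. Prior-half edges are excluded
from the evaluation universe — their relaxed shrinkage would otherwise rank
them on top and contaminate the comparison. Every stage derives its seed
from the master seed, so runs are bit-reproducible; the result carries a
manifest of seeds, grids and chosen penalties.

## Scoring, rank combination and evaluation

Fitted coefficients are rescaled to confidence scores
$S_{ij} = \sigma^2_j / (\sigma^2_j + \beta_{ij}^2\,\mathrm{var}(x_i))$,
where $\sigma^2_j$ is the fitted model's mean squared residual for gene
$j$. This approximation deliberately avoids refitting without each
predictor: a refit would discard exactly the information fusion
contributed. (The refit variant is available as `variant = "full_refit"`
for comparison.) $S = 1$ iff $\beta = 0$; smaller $S$ is better, and the
reported `confidence` is $1 - S$ so larger is better. Zero residual
variance with nonzero coefficients is floored at $10^{-12}$ and flagged.
Rankings order by ascending $S$ with lexicographic tie-breaking for
deterministic, diffable output.

`rank_combine()` implements the standard community baseline: per-network
average ranks (ties averaged), averaged per edge, re-ranked.
`evaluate_pr()` treats gold edges as unsigned positives over an explicit
eligible universe (self-edges excluded; optionally restricted to the
constrained or non-constrained subnetwork) and integrates precision over
recall by the step convention — the sum of precision at each true-positive
hit times $1/P$, i.e. average precision. AUROC comes from the
Mann–Whitney statistic. Signs are ignored in evaluation; sign-aware
assessment is out of scope.

## Transcription factor activity estimation

A TF's transcript level is often a poor proxy for its activity
(dimerization, ligands, phosphorylation). Given a prior network,
`estimate_tfa()` solves $P A \approx E$ for the activity matrix $A$, where
$P$ is the signed (±1) prior connectivity over prior-target genes and $E$
their expression, via the Moore–Penrose pseudoinverse; TFs without prior
targets keep their own expression, so an identity prior reduces the TFA
pipeline exactly to the expression pipeline (asserted in the tests —
the comparability contract between the two pipelines). Two caveats are
inherent to the method and documented rather than hidden: estimated
activities have arbitrary scale (standardization absorbs it, and recovery
comparisons are made on the unit-variance predictor scale), and when many
TFs share targets the pseudoinverse mixes their activities. The mixing is
negligible for realistically sparse priors (several non-overlapping targets
per TF) and severe for the very dense networks used in the fusion
simulations — which is why the TFA study below uses a sparser regime.

## The synthetic-data generator

`generate_study()` emulates everything the pipeline consumes, from one
master seed with per-stage substreams:

* **Orthology** — random one-to-one pairing between sources until a
  configured fraction of TFs (and, separately, of non-TF genes) is paired;
  pair counts are floored; the two pools never mix.
* **Networks** — coefficient entries are partitioned into fused groups
  (an entry plus everything reachable from it through true orthology on
  both the regulator and target side). With probability `sparsity` a whole
  group is zero; otherwise a shared $v \sim N(0,1)$ is drawn and each
  member set to $v + N(0, \sigma_f^2)$, so nonzero coefficients are
  $N(0, 1+\sigma_f^2)$ and cross-source differences of fused entries have
  variance $2\sigma_f^2$. Default $\sigma_f = 0.1$: related but not
  identical networks.
* **Expression** (`design = "timeseries"`) — first-timepoint expression
  $Y_{T1} \sim N(0, I)$ over all genes; $X_{T1}$ its TF columns;
  $Y_{T2} = Y_{T1} + X_{T1}\beta + \varepsilon$ with decay treated as zero,
  $\Delta t = 1$, and $\varepsilon \sim N(0, 0.1^2)$ by default (the noise
  level is a free parameter of the generator; 0.1 keeps the per-row signal-
  to-noise of a typical array experiment). First timepoints carry no
  predecessor and contribute no regression row.
* **Expression** (`design = "steady"`) — latent activities
  $A \sim N(0, I)$ drive targets at steady state (decay rate 1) while
  observed TF mRNA is $A$ plus noise with sd `tfa_noise_sd`; this is the
  world in which activity and abundance genuinely diverge, used by the TFA
  study.
* **Corruption** — a `fn_rate` fraction of true pairs is dropped and
  `round(fp_rate × #true)` false pairs are added among currently unpaired
  ids (the false-positive rate is expressed in units of the *true*
  ortholog count, mirroring how corruption levels are usually quoted);
  truth labels survive into the generated constraints.

What the generator does *not* emulate: multi-timepoint kinetics,
platform/batch effects, non-Gaussian expression noise, and operon
co-transcription. Passing tests therefore demonstrate correctness of the
machinery and the qualitative behavior of the penalties under the stated
statistical structure — not performance on any particular real compendium.

## Study conditions used by the tests and acceptance script

The simulation studies are scaled to run on one CPU in minutes; sizes are
the package's own choices, fixed once:

* *Fusion benefit*: 10 TFs × 50 genes, 75% orthology, sparsity 0.75,
  10 samples for the evaluated source and 40 for its relative, $\lambda_S$
  by CV; 10 seeds.
* *Subnetwork AUPR*: 20 TFs × 100 genes, sparsity 0.5, 15 samples per
  source ($p > N$, the under-constrained regime the method targets), 50%
  orthology for the constrained-subnetwork contrast and 90% for the
  spill-over contrast; $\lambda_S = 1$ vs 0.
* *Adaptive recovery*: 35 TFs × 100 genes, 60% true + 40% false orthology
  coverage (`fp_rate = 2/3`), 30 samples, $a$ at the 60th percentile,
  $\lambda_S = 1$.
* *TFA benefit*: 10 TFs × 100 genes at sparsity 0.9 (≈10 gold targets per
  TF, half entering the prior — enough for the pseudoinverse to be
  well-posed), `tfa_noise_sd = 2` so mRNA explains only ~20% of activity
  variance, the regime TFA estimation exists for. The steady-design ground
  truth has no TF-targeting edges, since TF transcript levels are exogenous
  there.

## Known limitations

* One shared decay rate; no per-gene $\alpha$.
* Jacobi sweeps converge slowly for extreme $\lambda_S$; use the direct
  solver (the default for ordinary component sizes) there.
* NCA-based TFA degrades when prior targets overlap heavily.
* Evaluation is sign-agnostic, and the confidence score is an
  approximation that inherits the fitted model's residual variance.
* No normalization or batch correction: inputs are assumed comparable
  within each source.
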