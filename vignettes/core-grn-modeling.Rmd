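---
title: "Modeling core gene regulatory networks with coregrn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling core gene regulatory networks with coregrn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coregrn)
```

## The problem

Two-state expression data — for example a disease cohort against matched
controls — rarely tells us *which* transcription-factor (TF) circuit
maintains the two states or which perturbations could move cells between
them.  `coregrn` addresses this by (i) enumerating many candidate TF-TF
networks from data, (ii) simulating the dynamics of every candidate with
an ensemble of random-parameter ODE models, (iii) selecting the candidate
whose simulated states best match the data while remaining controllable,
and (iv) screening in-silico knockdowns on the selected network.

## Candidate construction

Candidates are built from four ingredients: a log2 expression matrix with
two-group labels, a curated TF→target database (GMT), a TF–gene binding
probability table derived upstream from open-chromatin motif scanning,
and one or more externally ranked TF lists.

At a binding-probability threshold $\theta$, the accessibility-derived
targets of a TF are chosen from the $n_{genes}$ genes with probability
strictly above $\theta$: all of them if $n_{genes} < N_{TSH}$, otherwise
the top $\mathrm{round}(N_{TSH} + (n_{genes} - N_{TSH})\,p)$ by
descending probability ($N_{TSH} = 50$, $p = 0.01$ by default; rounding
is half-away-from-zero and probability ties break by gene identifier so
the selection is deterministic).  These targets are merged with the
curated sets, targets are restricted to measured genes, and TFs with
fewer than 8 targets are dropped.  The restriction happens *before* the
size filter so that counts reflect usable targets.

TF activity is inferred from target expression rather than the TF's own
transcript: each target row is z-scored and weighted $\pm 1$ by the sign
of its Spearman correlation with the TF's expression (or, when the TF is
unmeasured, by its loading on the targets' first principal direction),
and the weighted rows are averaged.  This signed-mean estimator is a
deliberately simple variant kept behind one function
(`infer_activity()`) so alternative estimators can be swapped in; what
downstream stages rely on is only the contract that activity separates
the two sample groups.  Activities are computed jointly on all samples
(the two groups share one standardization), and are recomputed for every
binding threshold because the merged database changes with it.

A directed edge $A \to B$ enters a candidate iff $B$ is a target of $A$
in the merged database and $|\rho_S(A,B)|$ strictly exceeds the
correlation cutoff; the sign of $\rho_S$ sets activation vs inhibition.
Self-loops are excluded by default because a row's correlation with
itself is uninformative.  The largest weakly connected component is kept
when it holds at least 80% of the TFs with any retained edge; candidates
below 15 TFs are discarded.  The grid defaults are the eleven binding
thresholds 0.05–0.20, TF counts per list {5, 10, 15, 20} (per-method
counts are study-specific, so the grid is fully configurable), and
twenty cutoffs $0.00, 0.05, \dots, 0.95$.

## Ensemble dynamics

Each gene $Y$ with regulators $X_i$ follows

$$\frac{dY}{dt} = \frac{G_Y}{\prod_i \lambda^{+}_{X_iY}}
  \prod_i H^s(X_i, X_iY_0, n_{X_iY}, \lambda_{X_iY}) - k_Y\,Y,
\qquad
H^s(X) = \lambda + \frac{1-\lambda}{1 + (X/X_0)^{n}},$$

where the leading product runs over excitatory in-edges only, so $G_Y$
keeps the meaning of a maximum production rate.  Kinetic parameters are
sampled uniformly per model: $G \in (1, 100)$ (arbitrary concentration
per time unit), $k \in (0.1, 1)$ (per time unit), integer Hill
coefficients $n \in \{1..6\}$, excitatory fold changes
$\lambda^{+} \in (1, 100)$, inhibitory fold changes as reciprocals of
draws from the same range, and thresholds
$X_0 \in (0.02M, 1.98M)$ with $M$ the Monte-Carlo median of $G/k$ — the
half-functional rule in its unregulated-median reading; a refinement
accounting for regulator modulation could be slotted in at
`estimate_median_threshold()` but is not the default.

Numerical choices: fixed-step Euler with $dt = 0.02$ over a horizon of
100 time units, convergence declared when
$\max_g |dY_g/dt| / \max(Y_g, \varepsilon) < 10^{-3}$ (checked every 25
steps, so most models exit early), one retry from a fresh random initial
condition on failure, and a flag otherwise; flagged models are excluded
downstream.  Initial conditions are log-uniform between
$(G/k)\prod\lambda^{-}/\prod\lambda^{+}$ and $G/k$ per gene.  Steady
states are strictly positive by construction (production is positive and
the Euler step cannot cross zero at $k\,dt \le 0.02$), and the package
re-checks the residuals of the governing equations directly
(`steady_state_residuals()`).  The integrator agrees with an adaptive
solver (deSolve's `lsoda`) to within 2% on toy circuits; this is tested.

Simulated profiles and experimental activities are compared in one
standardized space: log2 steady states z-scored per gene across
(converged) models, activity rows z-scored per TF across samples.  The
scales are otherwise incommensurate, so a shared standardization is
required before Euclidean distances are meaningful.

## Scoring, ranking, stability

A model is assigned to an experimental state by comparing its distance
to the nearest same-state sample with a null distribution of 1000
gene-label permutations of its own profile (one permutation set per
model, shared across states; $p$ is the fraction of null distances
$\le$ the observed one, without smoothing).  The model takes the
smallest-$p$ state if that $p \le 0.05$, and is otherwise unassigned.
Accuracy is the assigned fraction; proportions are over all models, so
control + case + unassigned = 1.  Flexibility is the mean Euclidean
shift of the (control, case) proportions over all single-TF knockdowns
(each knockdown multiplies the gene's production rate by 0.05 and
re-simulates from the stored parameters and initial conditions,
preserving the 1:1 model pairing).  Knockdown proportions for the
flexibility score reuse the same distance/permutation assignment; the
ridge mapper below belongs to the perturbation screen only.

Candidates are ranked separately by accuracy and flexibility (rank 1 =
highest), and the combined index is the sum of the two ranks; ties break
by higher accuracy, then fewer edges, then candidate id.  Stability of
the top candidates is assessed by re-scoring over repeated ensembles and
t-testing the top candidate's combined scores against each rival; within
a repeat, tied metric values receive tie-averaged ranks so identical
topologies score identically.  Per-candidate seeds are derived from the
master seed, the repeat index, and a topology hash, which makes results
independent of candidate order and of how work is distributed.

## Perturbation screen and annotation

For the selected network, the unperturbed models assigned by the
distance/null method train a ridge regression (penalty 1.0 on
standardized log2 states; the penalty is a default, not a fitted
quantity) of the class indicator, thresholded at 0.5.  Every knockdown
ensemble is classified by this mapper in the training standardization,
giving two-way proportions for all single knockdowns and for all pairs
among the union of the top-5 and bottom-5 singles ranked by
control-state proportion.  Shifts are tested with Pearson's chi-squared
without continuity correction — immaterial at ensemble-scale counts —
and profiles are projected onto principal components fitted on the
unperturbed ensemble only.

Each network TF is annotated with the pathway whose gene set is most
enriched (one-sided Fisher's exact test) in the TF's differentially
expressed regulon (the TF plus its targets, intersected with the DEG
list), provided $p \le 0.1$; ties break alphabetically.  The background
universe is the union of DEG-restricted regulons and pathway sets under
test — the natural choice when no explicit background is given — and is
configurable.  The differential-expression stage itself is a Welch
t-test with Benjamini–Hochberg adjustment and is input-pluggable: a
precomputed DEG table can be supplied instead.

## The synthetic generator

`make_planted_system()` plants a bistable circuit whose ground truth is
known: two TF modules, each TF inhibiting three TFs of the opposite
module, with sparse in-module activation (one edge for the first three
TFs per module).  The inhibition-dominant design is deliberate: under
the maximum-production normalization a gene whose excitatory inputs are
silent is produced at $G/\prod\lambda^{+}$, so activation-dominated
modules collapse into an all-low state, whereas mutual inhibition
between default-on modules yields two strong single-module-high
attractors.  Each TF additionally regulates 20 private target genes
(90% activating), and expression is Gaussian noise (SD 1 on the log2
scale) around state centroids separated by 2 SD, for 11 control and 9
case samples.  The curated database drops each planted entry with
probability 0.05 and adds ~2% spurious entries; the binding table gives
planted pairs probabilities in (0.5, 1) and background pairs (0, 0.3),
so every threshold on the usual grid separates them.  Decoy TFs with
random regulons and noise expression exercise the filtering stages.
Ranked TF lists are the planted TFs jittered by adjacent swaps, decoys
after.

What the generator does *not* emulate: probe/batch effects, dependence
between genes beyond the two-state mean structure, overlap between
regulons, read-level accessibility signal, and more than two cellular
states.  Passing the end-to-end tests therefore shows the machinery is
correct and calibrated on data that satisfies the model's assumptions;
it does not certify recovery on real cohorts.

## Problem sizes and test calibration

The test-suite and the acceptance script run the pipeline at a reduced
scale chosen to exercise every stage: 20 planted TFs, a
2 × 2 × 3 hyperparameter grid, 1000-model ensembles, and 500-permutation
nulls (unit tests use 1000 where the check is about null calibration).
Full-scale use (tens of candidates, 10,000 models, 1000 nulls) is the
package default.  Three statistical bounds in the tests are frozen from
oracles computed for the generator's own design rather than from rules
of thumb: DEG recall at a 2-SD shift with 11 + 9 samples has
Monte-Carlo power 0.84 ± 0.04 (bound 0.75); the expected silhouette of
two spherical Gaussian states at separation $d$ SD is
$1 - \sqrt{2/(2+d^2)} \approx 0.42$ at $d = 2$ (bound 0.35); and a
shuffled-label linear mapper overfits by roughly
$0.5\sqrt{p/n}$, so chance-level checks use $n \gg p$.

## Known limitations

Only two experimental states are supported; proportions and the mapper
are two-class by construction.  The activity estimator is a documented
simple variant, not a re-derivation of any published estimator.  Edges
exist only where the merged database supports them — no de-novo edge
learning.  Euler integration with the declared defaults can flag a few
percent of models in strongly inhibitory circuits; these are excluded
rather than re-solved with stiff methods.  The stability t-test treats
repeats as independent, which derived per-repeat seeds make true by
construction.
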