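---
title: "Predicting dendritic diameters from morphology: models, conventions, and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting dendritic diameters from morphology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Most reconstructed neuron morphologies in public repositories carry
reliable topology and coordinates but unreliable dendritic diameters:
light-microscopy tracing discretizes thin processes, and many archives
are submitted with a constant placeholder diameter. Diameter, however,
sets axial and membrane conductance, so compartmental simulations built
on such reconstructions misestimate time constants, input resistance and
synaptic attenuation.

`dendiam` predicts per-node dendritic diameters from features of the
morphology that do **not** depend on diameter, and provides a passive
cable simulator so the electrical consequences of the predicted
diameters can be compared against the original reconstruction.

## Node taxonomy and features

Every dendritic node (SWC types other than soma and axon) is assigned to
exactly one class:

* **initial** — the parent is a soma node (soma parentage wins over any
  other rule);
* **branching child** — the (non-soma) parent has two or more children;
* **continuing** — everything else.

Multifurcations are treated as branch points; the terminal-degree sum
runs over *all* children, not just two, because real reconstructions
contain trifurcations.

Seven features describe each node (micrometres throughout):

| Acronym | Meaning |
|---|---|
| D  | node diameter, `2 × radius` from the SWC file |
| PD | parent diameter; the soma diameter for initial nodes |
| IB | initial branch order: 1 at initial nodes, +1 below each branch point |
| TD | terminal degree: terminal tips contained in the node's subtree |
| PS | path length from the soma to the node |
| LP | longest downstream path to a terminal tip |
| TL | total downstream arbor length rooted at the node |

Conventions the format leaves open, fixed here and used consistently:

* distances are 3D Euclidean sums between consecutive nodes;
* the soma's own extent contributes 0 to PS — an initial node's PS is
  the Euclidean distance from its attached soma point;
* LP and TL of a terminal node are 0;
* the soma diameter used for PD of initial nodes is the diameter of the
  root soma node after soma normalisation.

These definitions satisfy exact conservation identities that the test
suite exercises: TD is additive at branch points,
`LP(parent) = step + max LP(child)`,
`TL(parent) = Σ (step + TL(child))`, and the sum of `TL + PS` over
initial nodes equals the cell's total dendritic length.

## The diameter models

For each node class (and tree label: apical, basal, or generic) a linear
model through the origin predicts diameter:

$$\hat D = \sum_j \beta_j f_j, \qquad f_j \in \{PD, IB, TD, PS, LP, TL\}$$

There is deliberately no intercept, and the goodness of fit is the
uncentered coefficient of determination
$R^2 = 1 - \mathrm{SSR}/\sum y^2$, adjusted as
$1 - (1-R^2)\,n/(n-p)$ — the standard convention for regression through
the origin. Adjusted $R^2$ can be negative and is reported unclipped.

Feature sets are chosen by a stepwise pair search with an *improvement
constant* (default 0.001; results are insensitive between 0.001 and
0.02): rank single-feature adjusted $R^2$; pair each feature, in
descending order, with every other; a pair wins only if it beats **both**
of its singles by at least the improvement constant and beats the best
qualifying pair so far. At most two features are ever selected, which
keeps every equation interpretable.

The package ships the published equation sets for hippocampal pyramidal
cells (apical and basal dendrites), cerebellar Purkinje cells and
striatal spiny projection neurons (pooled and per-archive variants) as
plain-text model files; `packaged_model_set("table4-hippocampal")` loads
one. One shipped equation deserves a caveat: the cerebellar
branching-children model carries a TL coefficient of 0.6842 µm per µm of
downstream arbor length, which produces implausibly large diameters on
arbors of realistic size. It is shipped verbatim — the package does not
silently correct published numbers — but loading or applying it emits a
prominent warning, and users with cerebellar data should refit that
model (`fit_model_set()`).

## Soma-outward prediction

`predict_diameters()` walks the tree in parent-first order. Initial
nodes are predicted from the soma diameter and their geometry; every
node further out sees its parent's *predicted* diameter as PD. The
geometry-only features (IB, TD, PS, LP, TL) are computed once from the
original morphology — they do not depend on diameter, so a single pass
suffices. Options:

* `keep_original_initial` — trust the reconstruction's initial-node
  diameters and predict only branching children and continuing nodes
  (initial nodes are thick and proximal, hence the best-measured part of
  most reconstructions);
* `min_diameter` (default 0.05 µm) — a floor applied to every
  prediction. The basal initial equation
  (−0.5964 PD + 0.3535 PS) is negative for short proximal paths; the
  floor keeps every output simulable;
* `uniform_diameter` — the constant-diameter control variant.

Because Pearson correlation is scale-free, a prediction that is a
constant multiple of the original scores $R^2 = 1$ in
`evaluate_prediction()`; the electrical comparison below is therefore
the sharper test. Per-tree $R^2$ is computed per morphology and tree
label, then averaged across morphologies, so large cells do not dominate.

## Passive electrical comparison

`build_compartments()` discretizes a morphology into one compartment per
SWC segment: membrane conductance and capacitance from the frustum's
slant lateral area, axial resistance from the exact frustum integral
$R_A L / (\pi r_1 r_2)$, and the soma as a sphere-equivalent compartment
of area $\pi d^2$ (soma normalisation rewrites any soma representation
into the canonical 3-point form first, preserving surface area to within
1%). Segments attached directly to the soma are cylinders of the node's
own radius — the soma's bulk contributes no dendritic membrane.

The solver is implicit backward Euler on the tree (default
`dt = 0.01 ms`), with one sparse Cholesky factorization reused across
steps; it is unconditionally stable on stiff trees and converges to the
exact steady state of the discretized system at any step size. Synaptic
conductance enters as an explicit current evaluated at the previous
step, accurate for picosiemens-scale inputs. Units are SI internally and
mV/ms/µm/nA/pS at every interface.

Default passive parameters are `RM = 1.6 Ω·m²`, `CM = 0.0186 F/m²`,
`RA = 1.98 Ω·m`. The resting potential is never part of the published
parameter set; the package defaults to `Em = −65 mV` and treats the
5 mV synaptic reversal as absolute (strongly depolarizing). Step-current
metrics are Em-invariant; the synaptic driving force is not, which is
why Em is exposed in `passive_params()`.

Three protocols summarize a morphology:

* brief pulse (1 ms, 1.5 nA at the soma): the decay is fit to
  $A_1 e^{-t/\tau_1} + A_2 e^{-t/\tau_2} + V_\infty$, initialized by
  log-linear peeling, the slower constant reported first. Pure
  single-exponential transients (e.g. an isopotential sphere) make the
  two-component problem singular; the fit falls back to one component
  and flags the result degenerate;
* prolonged step (800 ms, 30 pA): steady-state deflection ΔV as
  plateau minus baseline, with a slope check that warns when the plateau
  is not reached;
* dual-exponential synaptic conductance (10 pS, rise 1 ms, decay 5 ms)
  at a dendritic site: peak depolarization at the input site and the
  soma.

Predicted and original morphologies are compared metric-by-metric as the
normalized difference $|pred - orig| / |orig|$.

Analytic limits pin the implementation: an isopotential compartment
relaxes with $\tau = R_M C_M$ (29.76 ms for the defaults, matched within
0.1%); a sealed-end uniform cable reproduces the
$\cosh((L-x)/\lambda)/\cosh(L/\lambda)$ attenuation profile within 0.5%;
axial resistances of stacked frusta add exactly; and halving `dt`
changes $\tau_1$ and ΔV by less than 0.1%.

## Diameter autocorrelation

Why are some cell types predicted well and others poorly? The package
computes the correlation between diameters of nodes separated by
$k$ parent links ($k$ in node counts — the natural unit for chained
prediction; a path-distance-weighted variant would be a reasonable
alternative), averages it across an archive, and fits
$A_1 e^{-k/\lambda_1} + A_2 e^{-k/\lambda_2}$ with non-negative
amplitudes by nonlinear least squares (initialized from a log-linear
single-exponential fit, tolerance 1e-8, $\lambda_1 \le \lambda_2$ on
return). Long space constants mean diameter information survives many
prediction steps; short ones mean errors accumulate quickly, which is
exactly the regime where chained prediction degrades. An AR(1) diameter
sequence with coefficient $\rho$ is the analytic test case: its
autocorrelation is $\rho^k$, a single exponential with
$\lambda = -1/\ln\rho$, recovered within 10% in the suite.

## The synthetic-data generator

`generate_morphology()` grows a tree from a 3-point soma: `n_initial`
stems, per-node bifurcation probability `branch_prob`, Gaussian segment
lengths, directions drifting with a small angular jitter whose
z-component is kept small (so paths are genuinely 3D without the extreme
z-steps the validator reports). Diameters are then assigned soma-outward
by a ground-truth rule — any packaged or fitted model set, or an
arbitrary taper function — **exactly as the predictor chains them**,
plus truncated Gaussian noise (floored at `min_diameter`). By default
the noisy stored diameter feeds the child's PD, mimicking how
reconstruction noise propagates through a tracing; a flag switches to
noise-free chaining for exact-recovery tests.

Because the generator shares the predictor's chaining convention, a
noise-free generated cell is a fixed point: `predict_diameters()`
reproduces its diameters to numerical precision. That self-consistency,
plus parameter recovery (refitting archives of ≥5000 nodes at noise
σ = 0.05 µm returns every packaged coefficient within 5%), is the
desk-scale substitute for archive-scale validation.

The test and acceptance archives use per-cell-type geometries chosen
once to emulate each archive's feature scales: apical-like trees long
(segment mean 20 µm, depth 22) and sparsely branched (p = 0.12), so LP
and TL span hundreds of micrometres as in real pyramidal apical trees;
basal/spiny-neuron trees shorter and bushier; the hippocampal-basal
archive uses longer initial segments (mean 30 µm) because its initial
equation has a negative PD coefficient and is only positive — the regime
the published fit occupies — when the proximal path is long enough.
Selection-recovery replicates use 20 cells with 5 stems each: initial
equations are identified *across* cells (PD is the soma diameter, a
per-cell constant), so roughly a hundred initial nodes are needed before
the pair search has power.

What the generator does **not** emulate: diameter discretization from
light microscopy (the source of the high observed fraction of nodes with
D exactly equal to PD), tissue shrinkage, reconstruction topology
errors, and any correlation between topology and diameter beyond the
planted rule. Passing recovery tests therefore demonstrates correctness
of the machinery, not archive-scale predictive performance on real
neurons — on real data the published test-set correlations range from
R² ≈ 0.75 (apical, with original initial diameters) down to ≈ 0.1
(striatal), and the held-out synthetic check is accordingly run in the
apical model-match regime, where chained noise does not swamp the
geometric signal. Striatal-rule archives top out near R² ≈ 0.86 under
chained noise — the synthetic analogue of the fast-decaying striatal
autocorrelation.

## Numerical choices, edge cases, problem sizes

* SWC reading accepts unsorted ids, resolves parents after the full
  read, rejects dangling parents and cycles with the offending node
  named, and treats non-positive radii as warnings. The maximum
  inter-node z-step is reported but never acted on — exclusion is a
  curator's decision.
* Files are written at 4 decimals; round trips are lossless at that
  precision.
* Rank-deficient design matrices abort the fit naming the offending
  columns; classes with fewer than four nodes fall back to a PD-only
  model with a warning.
* Zero-length SWC segments are merged into the parent compartment with
  a warning.
* Tie-break for unexpected tree labels: a generic model applies
  silently; borrowing the basal model for an unlabelled tree warns.
* Test problem sizes were chosen to make every stochastic check
  well-powered while keeping the default suite around two minutes:
  recovery archives of 8–30 thousand nodes, 100 selection replicates,
  400-compartment cables, 1000-tree conservation sweeps.

## Known limitations

* Axonal diameters are out of scope; axon nodes pass through unchanged.
* Only passive membranes are simulated; active conductances would
  partially mask (or amplify) diameter errors.
* The linear, at-most-two-feature model family is a deliberate
  restriction; the 3/2-power branch rule is available as a diagnostic
  (`rall_check()`) but, matching the published analysis, is not used
  for prediction — it predicts the *sum* of child diameters, not the
  individual children.
* The cerebellar branch-children equation is shipped verbatim with a
  warning, as discussed above.
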