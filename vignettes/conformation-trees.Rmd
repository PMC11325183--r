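---
title: "Conformation trees by adaptive density clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformation trees by adaptive density clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conftree)
library(dplyr)
```

## The model

A long molecular simulation samples the Boltzmann distribution of a
force-field energy landscape: the deeper a local minimum, the denser the
cloud of visited conformations around it. After removing rigid-body motion
and reducing dimensionality, "find the energy wells and their hierarchy"
becomes a *density* problem in a low-dimensional Euclidean space. conftree
solves it with iterated DBSCAN.

DBSCAN with radius $\varepsilon$ and neighbourhood count $\mathrm{minpts}$
accepts density-connected sets whose local density exceeds

$$\rho_{\min}(\varepsilon) \;=\; \frac{\mathrm{minpts}}{V_d(\varepsilon)},
\qquad V_d(\varepsilon) = \frac{\pi^{d/2}\,\varepsilon^d}{\Gamma(d/2+1)},$$

so sweeping $\varepsilon_L = \varepsilon_{\mathrm{init}} + L\,\Delta\varepsilon$
for $L = 0, 1, 2, \dots$ scans the landscape from its densest cores outward:
each level's clusters contain the (possibly disconnected) clusters of the
previous level, and the run ends when one cluster holds every frame — the
root. Nodes of the resulting tree are density-connected conformational
ensembles; leaf depth in $\varepsilon$ measures how dense (deep) a well is,
and the $\varepsilon$ at which two branches merge measures how separated the
corresponding wells are: wells divided by lower barriers, whose point clouds
approach each other more closely in PC space, merge at smaller radii.

The pipeline around the sweep is conventional: Kabsch least-squares
superposition of all frames onto a reference, then PCA of the positional
covariance ("essential dynamics") and projection onto the leading $k$
components, then the sweep, then projection of per-frame metadata onto
nodes.

## Parameters that matter

* `eps_init` (nm in PC space): the first radius probed. It should sit at the
  typical nearest-neighbour spacing *inside* a well: much smaller and the
  first clustered levels fragment a single well into several transient
  cores (extra maximal-depth branches); much larger and shallow structure is
  skipped. This mirrors the manual bisection a practitioner performs —
  starting from a 2-D projection to gauge distances, then refining until the
  branch count is informative. `schedule_presets()` records parameter sets
  used for full-transporter analyses in a 10-D subspace
  (e.g. `eps_init = 3.7, delta_eps = 0.05, minpts = 4` for a cytosol-open
  ensemble); they are documentation, not defaults.
* `delta_eps`: the $\varepsilon$ resolution of the hierarchy. Smaller values
  give more levels (finer merge ordering) at linear cost in sweep length;
  reducing it is the remedy when a tree shows too few branches.
* `minpts` (default 4, self included): the noise threshold. Larger values
  suppress spurious micro-clusters in Gaussian tails at the cost of
  admitting frames into the tree later.
* `k` (`n_components`, default 10): the clustered dimensionality. DBSCAN
  degrades in very high dimensions, so `k` trades captured variance against
  clusterability; the explained-variance ratio reported by `glance()` on a
  fitted `conf_pca` is the diagnostic.
* `min_display` (default 5): annotation floor; nodes with fewer
  conformations of a type render white, so colour is only shown where the
  logarithmic intensity $I = \log_{10}(\mathrm{count}) /
  \log_{10}(\mathrm{total})$ is meaningful.

## Numerical and design choices

* **Determinism.** DBSCAN's only ambiguity is border points reachable from
  several clusters. conftree processes points in ascending frame index:
  clusters are numbered by their lowest member index and a border point
  joins the cluster of its lowest-index core neighbour. Parent assignment
  in the tree uses majority overlap with ties broken toward the candidate
  with the lower minimum member index — moot in practice, since the sweep's
  monotonicity (core points stay core, components only merge) makes nesting
  exact; `validate_tree()` reports the containment fraction and errors if
  it is below 1.
* **`minpts` counts the point itself**, matching the reading of "points
  expected within the hypersphere" and the dominant DBSCAN convention.
* **Covariance normalisation is $1/n$** (frames are the full sample), so
  per-component projected variance equals its eigenvalue exactly — an
  equality the tests assert at $10^{-6}$ relative tolerance. Component signs
  are fixed by making each component's largest-magnitude entry positive.
  Mass weighting is not applied; uniform weights are natural for
  carbon-α-only selections.
* **Units are nm internally**; PDB input (Å) is converted on load. Frame
  indices are 0-based everywhere and label tables declare that in a header.
* **Superposition reference** is the first frame of the concatenated
  ensemble, using all selected atoms; single-reference alignment is
  deterministic and standard for trajectory PCA. Atom selection (carbon-α,
  pocket subsets, …) is the caller's responsibility at load time.
* **Collapsing.** Consecutive levels with identical member sets extend one
  node, recording `[eps_first, eps_last]`; Newick branch lengths are the
  $\varepsilon$ span between child and parent births. Trees that never reach
  an all-frame root within `max_levels` (default 10,000) are returned as an
  explicitly flagged incomplete forest, never silently truncated.
* **Degenerate inputs.** Fewer than `minpts` frames is an error (no cluster
  can form); `n = minpts` identical points give a root at level 0; fewer
  than 3 non-collinear atoms cannot be superposed; a constant covariate
  cannot be cut into terciles.
* **Representative RMSD** defaults to superposition *on* (deformation
  only); both modes are exposed because published comparisons do not always
  state which was used. Intensities are normalised per label value (count
  in node over all conformations of that value), the only reading
  consistent with "full intensity for all conformations of the type".

## What the synthetic landscape does and does not emulate

`well_spec()` describes an isotropic Gaussian mixture; wells map directly
onto density modes, which is exactly the structure the sweep is meant to
recover, and `expected_merge_order()` (single linkage on inter-centre
distance minus width sum) provides the ground-truth merge sequence for
clearly separated wells. `sample_boltzmann()` adds Metropolis dynamics on
the implied energy surface $U = -\log f$ (burn-in 10% of steps, proposal
step half the smallest well width), reproducing the *temporal* character of
simulation data — dwelling and rare barrier crossings.

Real trajectories differ in ways the generator does not model: wells are
anisotropic and curved in PC space, frames are autocorrelated far beyond
what a Metropolis chain shows, sampling is non-equilibrium, and the PCA
subspace is itself estimated from the data being clustered. Passing the
test suite therefore demonstrates the algorithmic contracts — oracle-exact
DBSCAN, monotone nesting, correct well recovery and merge order under known
ground truth — not that any particular biological ensemble is summarised
faithfully; on real data the schedule parameters still require the manual
tuning described above. Barrier *height* in particular has no quantitative
definition in the generator: merge order is tested only in regimes where
centre separation is an unambiguous proxy (separation $\ge 8\times$ width).

## Problem sizes

The shipped tests and the acceptance script use fixtures of 200 frames per
well (400–1000 frames per tree, 1–10 dimensions, oracle comparisons up to
$n = 300$) — large enough that every property is exercised away from edge
cases, small enough to rebuild from scratch in seconds on one core. The
implementation itself is dense-matrix based ($O(n^2)$ distances, computed
once per tree); ensembles of a few tens of thousands of frames are
practical, and a spatial index would be an accelerator, not a correctness
change.

## A complete run

```{r demo}
spec <- demo_well_spec()
s    <- sample_gaussian_wells(spec, n = 600, seed = 42)
sup  <- superpose_frames(conf_ensemble(sample_points(s)))
proj <- project_frames(fit_pca(sup, k = 3), sup)
tree <- build_tree(proj, epsilon_schedule(0.3, 0.1, minpts = 4))
glance(tree)
validate_tree(tree)

labels <- tibble::tibble(frame_index = s$frame_index,
                         simulation_id = "demo",
                         well_label = s$well_label)
ann <- annotate_tree(tree, labels, "well_label")
autoplot(tree, annotation = ann)
```

The two leaves are the two wells; their colours are the pure cyan/magenta
of the generating labels, and the root (holding all frames of both labels)
mixes them.
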