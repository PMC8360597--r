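---
title: "Persistence vineyards for task fMRI: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Persistence vineyards for task fMRI: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmrivine)
```

## The model

At each time index $t$ an fMRI acquisition gives an amplitude
$f(x, y, z, t)$ on a fixed set of voxels.  fmrivine treats each time point as
a point cloud in a four-dimensional *stereotactic hyperspace*: the point
$(x, y, z, f_{\mathrm{norm}}(x, y, z, t)) \in \mathbb{R}^4$ for every voxel,
with the usual Euclidean metric.  Two voxels are close in hyperspace when
they are anatomically close *and* carry similar signal; a ring of voxels
whose amplitude differs sharply from its surroundings becomes a
non-contractible loop of the cloud.  The cloud's shape at every spatial
scale is summarized by truncated Vietoris–Rips persistent homology: each
homology class (component, loop, or void) has a birth radius and a death
radius, and its persistence (death minus birth) measures the geometric scale
it organizes.  Stacking the per-timepoint diagrams and linking loop classes
at consecutive time indices by the 3-D Hausdorff distance between their
representative cycles gives the *vineyard*; a temporally coherent, spatially
constrained chain of loop classes is a *vine*, and a vine whose presence or
persistence covaries with the task blocks is detected by a Wasserstein-based
permutation test.

### Assumptions

* Inputs are preprocessed (motion-corrected, unsmoothed or smoothed as the
  user prefers); the package does no fMRI preprocessing and no template
  registration.
* The voxel set is constant over time, so clouds differ only in their fourth
  coordinate.
* Computation is restricted to a region of interest (a few hundred to a few
  thousand voxels).  Whole-brain Rips persistence is out of computational
  reach and out of scope.

## Normalization

The amplitude is unitless while coordinates are spatial, so before embedding
the package applies the unique increasing **linear** map sending the
series-wide amplitude minimum to $a_0$ and maximum to $a_1$, where $a_0$
($a_1$) is the mean of the three per-axis coordinate minima (maxima).
Afterwards the amplitude range equals the average of the three coordinate
ranges.  The map is characterized by those two endpoint properties and has
no free parameters.  Two deliberate points:

* The map is *defined by the endpoint properties*, not by a ready-made
  rescaling such as $(f - a_0)/(a_1 - a_0)$; for a general amplitude range
  that expression does not land the extremes on $[a_0, a_1]$, so the
  endpoint characterization is what the code implements and tests.
* Extremes are taken over the **whole series**, not per time index.
  Per-timepoint normalization would erase amplitude dynamics across time and
  defeat the vineyard's purpose.
* A constant-amplitude series maps to the midpoint $(a_0 + a_1)/2$, the
  symmetric limit of the linear map.

Normalizing after a change of spatial units (all coordinates times $c > 0$)
scales every hyperspace distance, and hence every birth and death radius, by
exactly $c$; the test suite pins this to $10^{-9}$ relative tolerance.
`scale_amplitude()` exists only to probe the two degenerate limits: dialed
very high, the cloud stretches into a near-line and loop homology empties;
dialed very low, it collapses onto the voxel lattice whose only loop classes
are lattice squares born at half the voxel spacing.  (On a unit lattice
those square classes die at $\sqrt{2}/2$, i.e. $\sqrt 2$ times their birth
radius — the geometry forces $\sqrt 2$, and the unit-square test pins the
pair $(0.5, \sqrt 2/2)$ exactly.)

## Persistence computation

* **Radius convention.**  A simplex enters the filtration at *half* its
  diameter, matching the balls-of-radius-$r$ picture: two balls touch when
  $r$ is half the center distance.  All radii in diagrams, truncation and
  flags use this convention.
* **Coefficients** are GF(2), the standard choice for Rips persistence; it
  also makes representative cycles orientation-free.
* **Truncation.**  `r_max` (default 12, chosen to match the working range
  of the ROI-scale analyses the package targets) is a hard filtration cut.
  Classes alive at `r_max` are reported as truncated with `death = NA` and
  effective persistence `r_max - birth`; they are never assigned a fake
  death.  Raising `r_max` may only add features or finish truncated ones —
  it never changes an existing finite pair, and a test asserts exactly that.
* **Determinism.**  Simplices with equal radius are ordered by dimension and
  then lexicographic vertex tuple.  Lattice data is saturated with ties, and
  a total order makes the reduction — and therefore the representative
  choice — reproducible bit for bit.
* **Zero-persistence pairs** are dropped: they are invisible in any diagram
  and meaningless downstream.
* **Representatives.**  A finite loop/void class takes the cycle stored in
  the reduced boundary column that kills it; a truncated class takes the
  cycle accumulated in the column operations that zeroed its birth column.
  Representatives of a homology class are not canonical in any
  construction; what the package guarantees is that they are deterministic
  given the input, that the cycle is closed (every vertex of even degree),
  and that its youngest edge is the birth edge.
* **Dimension cap.**  `max_dim = 1` by default; the vineyard pipeline tracks
  loops.  `max_dim = 2` (voids) enumerates 3-simplices, which is
  combinatorially explosive, so it carries a hard point cap (400 points
  versus 2500 for loops).  The caps are guards against runaway enumeration,
  with an error advising a tighter mask or smaller `r_max`.
* **Oracle.**  `rips_persistence_bruteforce()` recomputes diagrams of small
  clouds by an independent route — homology ranks at every critical radius
  via GF(2) rank-nullity, with interval multiplicities by
  inclusion–exclusion — and the suite checks multiset equality against the
  engine on hundreds of random clouds in dimensions 0–2.

## Vineyard and vines

Edges connect **all** pairs of loop classes at consecutive time indices;
the shade of an edge is the linear clamp $\max(0, 1 - d/d_{\mathrm{ref}})$
of the 3-D Hausdorff distance $d$ between representative loops (amplitude
excluded: proximity means anatomical proximity).  Any monotone darkness rule
would do; the linear clamp is the simplest and makes shade 0 an exact
pruning criterion.  `d_ref` defaults to 4 stereotactic units — about the
diameter of the smallest loops the lattice can carry — and is configuration,
not science: it only affects rendering and pruning, never the test.

`extract_vine()` strips every diagram to the loop classes with persistence
at least 0.8 (the workflow's vine floor; truncated classes count
`r_max - birth`) whose representative centroid lies in a chosen stereotactic
box.  Centroid membership is robust to single stray vertices; strict
all-vertices membership is available.  Time indices with no retained class
stay as empty diagrams — intermittence is signal, not failure.

Region choice is the one manual step of the published workflow, so
`rank_vines()` provides a deterministic surrogate: greedy chains of loop
classes linked through representatives within `d_link` (default
`d_ref / 2`), scored by total persistence times chain length, each reported
with its padded bounding box.  It is validated only on synthetic ground
truth, where the planted loop's box is recovered.

## The permutation test

The published workflow names its ingredients — a Wasserstein-based
two-group statistic, labels permuted respecting the temporal and
experimental structure, several thousand permutations — without writing the
statistic.  The package implements the closest standard form, a joint
within-group loss:

$$S \;=\; \sum_{g \in \{1,2\}} \binom{n_g}{2}^{-1}
  \sum_{i < j \in g} W_q(D_i, D_j)^q,$$

with $W_q$ the exact $q$-Wasserstein distance on one homology dimension
(sup-norm ground metric, unmatched points pay their distance to the
diagonal, solved exactly by optimal assignment on the diagonal-augmented
cost matrix).  Defaults $q = 2$ and dimension 1; both exposed.  Small $S$
means the two groups are internally tight, so the p-value counts permuted
statistics $\le$ the observed one, with the plus-one estimator
$p = (1 + \#\{S_\pi \le S_{\mathrm{obs}}\})/(1 + n_\pi)$, which never
returns 0 and is valid under Monte-Carlo sampling.  `n_perm` defaults to
4999.

Labels are permuted at the **whole-block** level and only across the blocks
of the two tested conditions (consolidation blocks are excluded from both
groups): with 8 encoding and 8 retrieval blocks there are
$\binom{16}{8} = 12870$ equally likely assignments.  Block-level permutation
preserves within-block temporal autocorrelation, which is the reason the
null is credible for fMRI time series; an AR(1) noise option in the
generator exists to check exactly that.  Empty diagrams participate via the
all-to-diagonal matching, so the statistic sees both the vine's persistence
and its presence or absence.

## What the synthetic generators emulate — and what they do not

`task_series()` plants, on a small lattice, a ring of elevated amplitude
around a depressed core whose ring-minus-core contrast switches between
`contrast_on` at on-condition indices and `contrast_off` elsewhere, over
iid (optionally AR(1)) Gaussian voxel noise.  The reference conditions are
a 7×7×1 grid, ring radius 2, contrast 8, noise sd 0.5, with the 288-index
block design (4 conditions × 9 TRs × 8 cycles).  On that geometry the
planted loop is born near $0.7$ and dies near $1.8{-}1.9$, so its
persistence sits comfortably above the 0.8 vine floor while lattice noise
loops sit far below — a strong, clearly supra-threshold effect, which is
what the power claim is about.  The calibration study uses a reduced 5×5×1
grid with equal contrast in all conditions so that 200 replicates of the
full 288-index pipeline finish in minutes.

The generators deliberately do **not** model hemodynamic response
convolution, spatial autocorrelation, scanner drift or physiological noise
spectra.  Passing tests therefore demonstrate that the machinery recovers
and tests planted topological structure under white (or AR(1)) noise; they
do not certify behavior under realistic BOLD confounds.

## Numerical choices and degenerate inputs

* Diagram stacks fed to the vineyard may be pre-floored at the vine
  threshold (`persistence_floor = 0.8`): sub-floor features can never enter
  a selection, and dropping them early keeps the all-pairs edge stage small.
* Validation problem sizes: oracle equality on hundreds of clouds of ≤ 10
  points; geometry fixtures of 27–500 voxels; ring fixtures truncated at
  `r_max = 3` (every finite pair of interest dies below 3, and truncation
  cannot alter finite pairs); power and calibration at the reference and
  reduced grids above.
* Constant series, empty selections, empty-vs-empty diagrams and
  single-point clouds are all legal and tested; duplicate voxels, empty
  masks, inconsistent bounds and sub-minimum permutation counts are errors.
* Monte-Carlo reproducibility: every seeded entry point records its seed and
  restores the caller's RNG state; identical seeds give bit-identical
  results.

## Known limitations

* Representative cycles — and therefore edge shades — are deterministic but
  not stable: a small data perturbation can switch the chosen
  representative.  Diagram-level outputs (births, deaths, the test) are the
  stable quantities; tests assert determinism, not stability, of shading.
* One vine, one test: no omnibus multi-condition statistic and no
  multiple-testing correction across candidate vines.  Testing a region
  suggested by `rank_vines()` on the *same* data that ranked it is a
  selection effect the user must handle (pre-registration, split samples).
* The within-group statistic is a reconstruction of a cited-but-unwritten
  form; `q`, the statistic shape, and the handling of the untested
  conditions are documented configuration, not a claim about the original
  implementation.
* Rips persistence cost grows steeply with voxel count; the point caps are
  intentionally conservative.
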