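---
title: "Probabilistic neuron reconstruction with NeuronSMC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic neuron reconstruction with NeuronSMC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NeuronSMC)
```

# The problem

Single-neuron morphometry needs a digital reconstruction of the cell's
branching tree -- an SWC file of connected nodes with positions and radii --
from a 3D fluorescence microscopy stack. Manual tracing does not scale, and
automated tracing must cope with photon noise, uneven intensity, gaps, and
strongly anisotropic voxels. NeuronSMC reconstructs one neuron per stack
fully automatically with a probabilistic tracer: instead of committing to a
single deterministic path, each branch is traced many times by a particle
filter, and the redundant, statistically independent traces are merged into
a consensus centerline.

The pipeline has six stages: soma extraction, seed extraction, branch
tracing, trace refinement, node grouping, and tree construction. A
companion simulator renders any SWC morphology into a synthetic stack with
controlled signal-to-noise ratio (SNR) and inter-voxel correlation (COR),
so that every stage is testable end-to-end against a known ground truth.

# Soma extraction

The cell body is much thicker than any neurite, so grayscale erosion with a
structuring element of radius $r_s$ (a separable minimum filter, half-width
$r_s$ per axis, divided by the z aspect along z) removes all branches and
leaves only the eroded soma. The eroded stack is smoothed with a Gaussian
of $\sigma = r_s$, rescaled to 8 bits, and segmented by max-entropy (Kapur)
thresholding; the largest connected component becomes the soma blob. The
model kept for tree building is a single sphere: the blob centroid, with
radius equal to the mean distance of blob voxels to the centroid (for an
ideal ball of radius $R$ this statistic is $3R/4$).

Absence of a soma must be decided explicitly, since thresholding always
produces some blob. Two rules reject false detections: the fitted radius
must be at least $r_s$ (the soma must exceed the branch scale by the
construction of $r_s$), and the blob must be foreground in the *original*
image -- its mean intensity at least one global standard deviation above
the image median. The second rule matters because erosion of a branch-only
stack leaves an almost flat background field whose min-max rescaling
amplifies noise into plausible-looking blobs; those blobs sit at background
intensity in the original image and are rejected. Setting $r_s = 0$
disables soma detection entirely, and the reconstruction is then rooted at
the strongest group node.

# Seed extraction

Seeds are points with a high probability of lying on a branch centerline.
For each scale $\sigma$ in the configured set, the Hessian of the
Gaussian-smoothed image is computed by separable Gaussian-derivative
filtering (responses normalized by $\sigma^2$; the derivative scale along z
is divided by the z aspect). With eigenvalues ordered
$|\lambda_1| \le |\lambda_2| \le |\lambda_3|$, the tubularity is

$$\upsilon = \left(1 - e^{-\mathcal{R}_a^2 / 2\alpha^2}\right)
             e^{-\mathcal{R}_b^2 / 2\beta^2}
             \left(1 - e^{-\mathcal{S}^2 / 2c^2}\right),$$

zero whenever $\lambda_2 > 0$ or $\lambda_3 > 0$ (bright tubes on a dark
background have two strongly negative eigenvalues), with
$\mathcal{R}_a = |\lambda_2|/|\lambda_3|$ separating tubes from plates,
$\mathcal{R}_b = |\lambda_1|/\sqrt{|\lambda_2\lambda_3|}$ penalizing blobs,
and $\mathcal{S} = \sqrt{\lambda_1^2 + \lambda_2^2}$ the structureness. The
constant $c$ is set once to half the *maximum Hessian norm over all scales*
(`cFrac = 0.5`). This global choice is deliberate: recomputing $c$ per
scale normalizes the structureness factor to the same range at every scale,
which flattens scale selection -- on a solid radius-3 tube the per-scale
variant selects $\sigma = 6$ and the resulting template correlations drop
to the termination threshold, starving the tracer of seeds. With the global
constant the selected scale tracks the tube radius. A `frobenius` switch
enables the all-eigenvalue structureness variant; the two-eigenvalue form
is the default.

Per voxel the maximum $\upsilon$ over scales is kept, along with the
winning $\sigma$ and the eigenvector of $\lambda_1$ (the local branch
axis, sign-normalized to a non-negative z component since branches are
traced in both directions anyway). Seed candidates are local maxima of the
tubularity map under a noise tolerance $\tau$: candidates are processed in
decreasing value and one survives only if its flood region (connected
voxels within $\tau$ below it, on the map affinely rescaled to 0--255)
touches neither a higher voxel nor the claimed territory of a higher
maximum -- the classic interactive maxima-finding semantics, generalized to
26-connected 3D. Survivors then pass cylindrical non-maximum suppression
(strict maximum over an oriented cylinder of radius $3\sigma$ and total
length $\sigma$; value ties break toward the lexicographically lower
position) and a final correlation filter: the seed's pose must correlate
with the cylindrical template at least as well as the tracer's own
termination threshold $c_{\min}$.

# Branch tracing

A trace is a sequence of hidden states $x_i = [p_i, v_i, \sigma_i]$
(position, unit direction, scale). The posterior over states given the
image measurements is approximated with $N$ weighted particles, updated
per step in three moves:

* **Predict.** Each particle draws a new direction from a von Mises-Fisher
  distribution with concentration $\kappa$ about its previous direction
  (sampled exactly on the sphere by inverse-CDF of the axial cosine), a
  step length from a Gaussian with mean $d$ and standard deviation $d/3$
  truncated to $(0, 2d]$, and a new scale from a Gaussian about the
  previous scale with standard deviation $\zeta$, truncated to scale moves
  of at most $3\zeta$ and clamped to $[0.25, \max(\text{scales}) + 3\zeta]$
  so the template stays well-posed. The stored direction is the normalized
  displacement between consecutive positions.
* **Update.** The likelihood is $e^{K c}$ where $c \in [-1, 1]$ is the
  zero-normalized cross-correlation between the image (sampled
  trilinearly, border values replicated) and a cylindrical template with
  Gaussian cross-section $e^{-(k^2+l^2)/2\sigma^2}$, constant along the
  axis; support is $\lfloor -3\sigma\rfloor \le k,l \le \lceil 3\sigma
  \rceil$ across the axis and $\lfloor -\sigma\rfloor \le m \le \lceil
  \sigma\rceil$ along it, a band centered on the state so the correlation
  measures the local cross-section on both sides. Weights multiply the
  previous weight, the transition density (evaluated up to a constant --
  normalizers cancel in the renormalization), and the likelihood, then
  renormalize. If every weight underflows the set resets to uniform with
  a warning.
* **Resample and estimate.** When the effective sample size
  $1/\sum_k w_k^2$ drops below $0.8N$, systematic resampling (one uniform
  offset against the cumulative weights) replaces the set with equally
  weighted offspring. The emitted trace node is the weighted centroid of
  the particle positions and scales, with the direction renormalized (the
  previous direction is kept if the weighted mean degenerates).

Each seed is traced twice, along $+v$ and $-v$, and the two half-traces
are joined through a node at the seed so every kept trace is one connected
polyline. Tracing stops when the unweighted mean correlation falls below
$c_{\min}$ (end of branch), at the iteration limit $L$, when the estimate
leaves the volume, or when the local node density exceeds $\delta_n$ --
a shared counter grid over all traces, with $n \in \{1, 5, 9\}$ covering
the voxel alone or its in-plane 4- or 8-neighborhood (in-plane because
stacks are typically anisotropic in z). The density check runs against a
node's own neighborhood *before* the node is appended, so a single voxel
can accumulate at most $\delta_n + 1$ nodes. Over-tracing the same branch
from many seeds is intentional: each pass is probabilistically
independent evidence that the refinement stage exploits.

# Trace refinement, grouping, and tree construction

All traces are first resampled to a 1-voxel step (radii and correlations
interpolated linearly). Mean-shifting then moves every node to the
unweighted mean of the nodes within its own *initial* radius (a flat
kernel; distances anisotropy-aware), synchronously across nodes, for 5
iterations -- enough for radially scattered redundant traces to collapse
onto a consensus centerline. Refinement changes estimates only: node count
and links are untouched.

Grouping collapses the redundancy: repeatedly take the ungrouped node with
the highest correlation (ties toward the lower index) and merge it with
every still-ungrouped node within radius $r_g$ into one group node whose
fields are unweighted member means. Links between refined nodes project
onto their groups, so connectivity established by any trace survives.
Finally, breadth-first search converts the bidirectional group graph into
a parented tree, rooted at the soma sphere (with every group center
within soma radius plus group radius attached to it) or, without a soma,
at the highest-correlation group node. Back-edges (cycles) are dropped by
the traversal. Disconnected components with at least `minComponent = 3`
groups are emitted as extra roots; smaller ones are discarded as isolated
false positives, and single-node terminal twigs hanging off junctions are
pruned by default (`prune = TRUE`).

# Parameters

| name | default | unit | role |
|------|---------|------|------|
| `rs` | 6 | voxels | erosion radius; 0 disables soma detection |
| `scales` | \{2, 4, 6\} | voxels | tubularity scale set |
| `tau` | 10 | 8-bit | maxima noise tolerance |
| `N` | 20 | -- | particles per trace |
| `kappa` | 3 | -- | direction concentration (smaller = more curvature) |
| `d` | 3 | voxels | step length mean |
| `zeta` | 1 | voxels | scale transition sd |
| `K` | 20 | -- | likelihood sensitivity |
| `cMin` | 0.5 | -- | seed filter and termination correlation |
| `L` | 200 | steps | iteration limit per trace |
| `deltaN` | 4 (n = 9) | nodes | density limit per neighborhood |
| `rg` | 2 | voxels | grouping radius |

The defaults are the method's standard operating point and are used
unchanged in the end-to-end tests. `reconstructionConfig()` bundles them,
a YAML file with the same field names can override any subset
(`readConfig()`), and every pipeline command records a provenance sidecar
(configuration, seed, package version) sufficient to replay a run.

# The simulator and what passing tests mean

`simulateStack()` renders a morphology as the union of tapered capsules
(cone frusta with hemispherical caps between parent and child, matching
the per-node radii of the SWC convention) and computes each voxel's
occupied volume fraction on a supersampled subgrid. Optics are reduced to
this partial-volume effect: at typical magnifications the voxel is larger
than the point spread function, so digitization dominates optical blur and
no PSF is convolved. Noise is Poisson per voxel with expectation
$\lambda_b + \text{occ} \cdot (\lambda_f - \lambda_b)$, where the
foreground level solves $(\lambda_f - \lambda_b)/\sqrt{\lambda_f} =
\text{SNR}$ (the background level defaults to 10 expected photons --
unstated by convention, chosen nonzero to keep that equation well-posed
and images realistic). A COR level $> 0$ smooths the noisy stack with a
Gaussian of that scale (divided by the z aspect along z), then restores
the SNR: because an affine rescaling moves contrast and noise together,
the restoration instead adds a scaled copy of the smoothed noise-free
expectation, root-solving the scale factor so the measured SNR re-matches
the target. The measurement uses interior voxels (occupancy
$\ge 0.999$, falling back to $\ge 0.5$ when a thin morphology has fewer
than 100 interior voxels): partial-volume edge voxels carry a signal
gradient that would otherwise dominate the "noise" standard deviation and
make the calibration unsolvable at high COR. Output is one min-max scaled
8-bit TIFF page per z slice.

The simulator emulates photon-limited single-neuron fluorescence imaging
with controllable difficulty; it does not emulate PSF anisotropy, uneven
staining, autofluorescent clutter, multiple cells, or camera gain and read
noise. Tests passing on these phantoms therefore demonstrate the
correctness and noise robustness of the algorithmic chain, not performance
on any particular real data set.

# Numerical choices and degenerate inputs

* Coordinates are voxel units, 0-based, a node at an integer position at
  the center of that voxel; anisotropy enters only through the per-axis
  aspect applied to coordinate differences (1:1:2 assumed when the voxel
  size is unknown).
* The scale-move truncation is read as a bound on the *change*
  $|\sigma_i - \sigma_{i-1}| \le 3\zeta$; an absolute cap at $3\zeta$
  voxels would contradict tracing at scales up to 6.
* The template frame is $u = \widehat{v \times a}$, $w = v \times u$ with
  $a = \hat z$ unless $|v_z| > 0.9$ (then $a = \hat x$): deterministic and
  smooth almost everywhere.
* Truncated Gaussians are sampled by inverse-CDF, so fixing the RNG seed
  makes whole reconstructions bit-reproducible; all randomness flows from
  R's RNG.
* Degenerate cases are defined, not exceptional: empty trees voxelize to
  zero with a warning, constant images yield no maxima and zero
  correlation (flagged, never NaN), an all-zero weight update resets to
  uniform with a warning, empty traces and empty reconstructions are
  legal outputs, and scoring an empty tree is an error.
* Mean-shift updates are synchronous (Jacobi-style); the update order is
  therefore irrelevant and results are order-independent.
* Ties break deterministically everywhere: maxima by processing order
  (value, then linear index), cylindrical suppression lexicographically by
  position, grouping toward the lower node index, thresholds toward the
  lower bin.

# Scope of the shipped experiments

The test suite and the acceptance script run on phantoms sized for
interactive turnaround: straight cylinders of radius 2--7 in stacks up to
$160 \times 40 \times 40$, a 60-voxel Y-shaped bifurcation phantom in a
$72 \times 64 \times 24$ stack, and the end-to-end experiment at SNR
$\{2, 4, 20\}$, COR 0, with 5 simulation replicates per level. These sizes
exercise every code path (multi-scale seeds, bidirectional tracing,
density limiting, merging, soma-less rooting) while keeping a full run in
minutes; the pipeline itself has no dependence on these sizes, and the
full factorial study grid (10 morphologies x 7 SNR x 5 COR levels = 350
stacks) is enumerated by `syntheticGridConditions()`.

# Known limitations

* One neuron per stack: no multi-soma segmentation or forest semantics
  beyond keeping large disconnected components.
* The soma is a single sphere; irregular cell bodies are summarized, not
  delineated.
* The tracer is single-branch: bifurcations are recovered by independent
  traces from different seeds meeting in the group graph, not by a
  branching-aware filter, so a bifurcation missed by seeding is missed
  entirely.
* Radius estimates come from the template scale and are coarser than the
  centerline positions, especially for branches thinner than the smallest
  configured scale.
* Grouping is greedy first-claim; a node within $r_g$ of two candidate
  centers joins whichever group forms first (highest correlation).
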