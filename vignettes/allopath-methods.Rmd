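---
title: "Detecting allosteric communication paths from dihedral mutual information"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting allosteric communication paths from dihedral mutual information}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allopath)
```

## The model

`allopath` treats allosteric communication as statistical dependence between
residue backbone motions. The observable is the φ torsion
C(i−1)–N(i)–CA(i)–C(i), chosen because it exists for every amino acid except
a chain's first residue and because internal angles, unlike Cartesian
coordinates, are invariant to rigid-body motion and so do not pick up
spurious whole-molecule correlations. Dependence between two residues is
measured by normalized mutual information on histogram estimates:

$$\mathrm{MI}(X,Y)=\sum_{x,y} P(x,y)\log_2\frac{P(x,y)}{P(x)P(y)},\qquad
\mathrm{NMI}(X,Y)=\frac{\mathrm{MI}(X,Y)}{\sqrt{H(X)H(Y)}}\in[0,1],$$

with $H$ the Shannon entropy of the marginal histogram (bits). NMI feeds a
residue contact graph: nodes are residues, edges join residues whose closest
heavy atoms lie within the contact cutoff, edge weight = NMI. A
communication path between two spatially distant residues is the route
through this graph that maximizes cumulative NMI; one best path is traced
per eligible pair and the highest-scoring `top_k` paths form the result set,
which is then clustered into distinct spatial routes and probed for
stability by bootstrap.

Assumptions worth stating plainly: (i) the simulation samples a single
conformational basin well enough that histograms are meaningful — the method
measures coupling within a state, not transitions between states; (ii)
backbone φ captures the relevant signal (side-chain χ and ψ dynamics are not
used); (iii) contacts are taken from a static frame selection, so large
conformational rearrangements that make and break contacts during the
trajectory are not tracked.

## Parameters, defaults and rationale

| parameter | default | units | why |
|---|---|---|---|
| `bins` | 36 | — | 10° equal-width bins on the fixed support [−180°, 180°). Fixed edges make results independent of trajectory content; 36 bins resolve rotameric basins while keeping the 2-D histogram (36² cells) populated at typical frame counts (10²–10⁴). |
| `contact_cutoff` | 5 | Å | minimum heavy-atom distance defining a residue contact (inclusive). |
| `min_separation` | 12 | Å | minimum source–target separation for path tracing (inclusive); below this, "communication" is trivial adjacency. |
| `top_k` | 500 | — | paths retained after ranking by cumulative NMI; ranking suppresses noise paths. |
| `overlap_cutoff` | 12 | Å | residue-pair distance under which two paths are considered spatially overlapping for clustering. |
| `transform` | `one_minus` | — | Dijkstra edge cost; see below. |
| `bootstrap_B` | 500 | — | frame-resampling replicates (0 skips). |
| `seed` | 0 | — | controls all randomness; identical configs reproduce byte-identical outputs. |
| `r_min`, `r_max` | 0.1, 0.6 | Å | spline radius range; radius is linear in within-cluster traversal count. |

`distance_frames` selects which frames define the distance matrix: the first
frame (default — cheap and deterministic), all frames (minimum over the
trajectory), or explicit indices. This choice is exposed because contact
definitions over a trajectory are genuinely ambiguous; for equilibrated
single-basin simulations the first frame is representative.

## Numerical and design choices

**Dijkstra maximization transform.** Dijkstra requires nonnegative costs, so
maximizing cumulative NMI is mapped to minimizing edge costs
$c_e = 1-\mathrm{NMI}_e \in [0,1]$; the reported score is $\sum_e
\mathrm{NMI}_e$. This transform penalizes long low-NMI detours while still
rewarding genuinely informative multi-step routes. Alternatives
(`1/NMI`, `−log NMI`) are available via `transform`. One consequence: adding
edges (raising `contact_cutoff`) monotonically lowers the minimized *cost*,
but can lower the reported *score* of the optimum when a shortcut with fewer
hops wins — score is not monotone in the cutoff and the test suite asserts
monotonicity of the cost, which is the quantity actually optimized.

**Degenerate entropies.** A motionless residue has $H=0$; its NMI is defined
as 0 (it carries no communicable signal), avoiding division by zero. For a
residue pair, frames in which either φ is undefined are dropped pairwise and
the entropies in the normalization are taken from the joint table of the
retained frames, so MI and its normalization always describe the same
sample.

**Estimator bias.** The histogram MI estimator has a positive finite-sample
bias of order $(\text{bins}-1)^2/(2N\ln 2)$ bits; no correction is applied.
The bias is shared by all pairs and matters only near the noise floor; tests
assert the floor stays below NMI 0.1 at 5000 frames.

**Ties and determinism.** Ranking ties are broken lexicographically on the
canonical residue-index sequence; each path is stored in canonical
orientation (lower endpoint first), so (s, t) and (t, s) queries produce the
identical object and bootstrap occurrence matching is well defined. The
silhouette scan prefers the smallest k on ties. With fewer than 3 paths, or
an all-zero dissimilarity, clustering degenerates to a single cluster with a
warning rather than an error.

**Angle conventions.** Angles are degrees in [−180°, 180°); the torsion is
the standard atan2 normal-vector formula (a planar *trans* quartet is 180°,
stored as −180). Near-collinear quartets yield `NA` with a warning.

**Dissimilarity normalization.** The spatial overlap count between paths p
and q is normalized as $d = 1 - \mathrm{overlap}/(|p|\cdot|q|)$, bounding d
in [0, 1] and removing the bias whereby long paths overlap more in absolute
terms. Average linkage is the default because the overlap dissimilarity is
non-Euclidean; complete/single linkage are accepted.

**Bootstrap statistic.** Frame resampling uses one index vector for all
residues, preserving the per-frame cross-residue coupling that the method
measures; graph topology and distances are held fixed (resampling frames
does not move atoms). The stability statistic is the per-replicate count
$n_b$ of original top-k paths recovered (matched by canonical residue
tuple), summarized as $\mathrm{SE} = \mathrm{sd}(n_b)/\sqrt{B}$ — one number
per system. A per-path occurrence-frequency statistic would be a reasonable
alternative; the count statistic was chosen because it is directly
interpretable against k and its degenerate cases are exact (identity
resampling gives SE = 0).

## The synthetic generator: what it emulates, and what it does not

`make_coupled_trajectory` plants correlated φ motions with a hidden
categorical state: each frame draws a latent symbol $z$ out of $m$ (default
4) angular sectors; every coupled residue's φ falls in sector $z$ with
probability $\kappa + (1-\kappa)/m$ and in a uniformly random sector
otherwise, uniformly within the sector. This model was chosen over, say,
autoregressive angular dynamics because its sector-level MI has a closed
form (`coupling_model_nmi`), giving an analytic oracle: κ = 0 is exact
independence, κ = 1 gives MI = log₂ m and NMI = 1 under sector-aligned
binning. Carbonyl carbons are rotated about their N–CA axes frame by frame
so the produced coordinates reproduce the planted angles through the actual
dihedral code to ≪ 10⁻³ degrees, and the fixture PDB/DCD writers live in
this module — separate from the production readers — so round-trip tests
cross the module boundary.

Default study conditions used by the tests and the acceptance script: a
10-residue chain at 3.8 Å Cα spacing, κ = 0.9, m = 4, 5000 frames for
planted-path recovery; a 2 × 8 two-chain ladder at 1200 frames for bootstrap
stability (B = 50, k = 10); 200 random graphs of ≤ 10 nodes for Dijkstra
optimality; 2–3 bundles of 10 paths for clustering recovery. These sizes
make every stage's expected outcome derivable while exercising the same
code paths as a full protein system.

What the generator does **not** emulate: force-field energetics, correlated
*sequences* of frames (frames are i.i.d., so autocorrelation-aware block
bootstrap questions cannot be studied), side-chain motion, contact networks
that rearrange over time, and the sheer pair count of a real receptor
(hundreds of residues). Passing tests therefore demonstrate correctness of
the estimator, the graph search, the clustering and the bootstrap under
known truth — not that a particular biological system's paths are
recoverable from a given simulation length.

A geometric consequence worth noting: a single synthetic chain whose
adjacent residues are within 5 Å while residues ≥ 4 apart exceed 12 Å
necessarily yields a *line* contact graph (triangle inequality), so route
identity is topologically forced there. The chain fixture is therefore used
to test signal recovery and score collapse under κ = 0, while the two-chain
ladder — whose cross-chain rungs create alternative routes — is used to test
route *stability* under bootstrap, where coupling strength genuinely changes
which routes win.

## Limitations

- φ-only: couplings expressed through side chains or ψ are invisible.
- Histogram MI needs enough frames per occupied bin; very short
  trajectories inflate the noise floor (reduce `bins` in that regime).
- One best path per residue pair; k-shortest-path enumeration per pair is
  out of scope, as are centrality analytics.
- Contact topology is static per analysis; the bootstrap varies weights
  only.
- The full analysis is O(pairs × Dijkstra) and the NMI matrix is
  O(residues² × frames); for large systems cache the NMI matrix
  (`write_nmi_csv`/`read_nmi_csv`) between runs.
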