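# allopath

Allosteric communication path analysis of molecular dynamics (MD)
trajectories from dihedral-angle mutual information.

Allostery — the modulation of a protein site by a perturbation at a distant
site — propagates through networks of correlated residue motions. `allopath`
detects and ranks such communication paths directly from an MD simulation
(a PDB topology plus a DCD trajectory), for structural biologists and
computational chemists studying receptors, kinases and other allosterically
regulated proteins.

## Method

1. **Dihedral extraction.** For every residue the backbone φ torsion
   C(i−1)–N(i)–CA(i)–C(i) is computed per frame (φ is present in every
   amino acid; internal angles avoid the spurious correlations that
   Cartesian coordinates introduce).
2. **Normalized mutual information.** For each residue pair the φ series
   are discretized into equal-width histograms on [−180°, 180°) (36 bins by
   default) and

   MI(X,Y) = Σₓ Σ_y P(x,y) log₂ [ P(x,y) / (P(x)·P(y)) ],
   H(X) = −Σₓ P(x) log₂ P(x),
   NMI(X,Y) = MI(X,Y) / √(H(X)·H(Y)) ∈ [0, 1].

3. **Contact graph.** Residues are nodes; edges connect residues whose
   minimum heavy-atom distance is within 5 Å, weighted by NMI.
4. **Path tracing.** For every residue pair separated by at least 12 Å,
   Dijkstra's algorithm finds the route minimizing Σ(1 − NMI) over edges —
   i.e. maximizing cumulative NMI per step — and the 500 highest-scoring
   paths (score = Σ NMI) are retained.
5. **Route clustering.** Paths are grouped by a spatial-overlap
   dissimilarity d(p,q) = 1 − overlap(p,q)/(|p|·|q|) (overlap counted at a
   12 Å cutoff), with average-linkage hierarchical clustering and the
   cluster count chosen by silhouette score.
6. **Stability.** Bootstrap resampling of trajectory frames (same index
   vector for all residues) reruns the whole analysis; the overlap of each
   replicate's top-k set with the original is summarized as
   SE = sd(n_b)/√B.
7. **Export.** Clustered paths become Catmull–Rom splines anchored to
   Cα atoms, radii scaled by within-cluster traversal frequency, written as
   a PyMOL CGO script, a JSON payload and a binary STL mesh.

A synthetic-fixture module (`make_chain_structure`,
`make_coupled_trajectory`, `make_planted_bundles`) plants tunable dihedral
correlations with a closed-form NMI, so the full pipeline is testable
without external trajectories.

## Worked example

```r
library(allopath)
s   <- make_chain_structure(10)                                # 10-residue chain
sim <- make_coupled_trajectory(s, frames = 2000, kappa = 0.9,  # planted coupling
                               seed = 1)
fit <- allopath(s, sim$trajectory, top_k = 50)
summary(fit, n = 5)
```

```
Allosteric communication path analysis
  system: 10 residues, 2000 frames
  NMI: 9 residues, 36 bins
  graph: 9 nodes, 8 edges (contact cutoff 5 A)
  paths: 15 retained of 15 candidates (top 50 )
  clusters: k* = 3 

Top paths:
 source target length    score
    A:2   A:10      9 2.445560
    A:3   A:10      8 2.140716
    A:2    A:9      8 2.134301
    A:4   A:10      7 1.836012
    A:3    A:9      7 1.829456
```

The top-ranked path runs A:2 → A:10 straight along the planted coupled
chain: 9 residues, cumulative NMI 2.45 (about 0.31 per contact, against a
finite-sample noise floor near 0.03). Residue A:1 carries no φ (no
preceding carbonyl carbon) and is excluded. `write_outputs(fit, "out/")`
writes the ranked paths (JSON/TSV), cluster payload, NMI cache, viewer
script and STL mesh; `plot(fit)` shows the NMI heatmap and the silhouette
profile. A command-line front end is installed as `exec/allopath`
(`--lig "A:2,A:3"` restricts tracing to ligand-contact residues; `--motifs`
counts occurrences of named residue sets such as GPCR microswitches).

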