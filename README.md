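# PSNet

Contact-based **Protein Structure Networks** (PSNs) from multi-frame
structural ensembles, for structural biologists who analyze molecular
dynamics (MD) trajectories or multi-model PDB ensembles at the
residue-interaction level.

## The method

A PSN represents a protein as a graph: nodes are residues (all except
glycine, which has no side chain), represented by the mass-weighted
**center of mass (COM) of their side-chain atoms**; a frame-level contact
exists when two COMs are within a distance cutoff *c*; and over an
ensemble of *F* frames the edge weight is the contact **persistence**

&nbsp;&nbsp;&nbsp;&nbsp;*w<sub>ij</sub>* = (100 / *F*) · #{ *f* : ‖*r<sub>i</sub><sup>(f)</sup>* − *r<sub>j</sub><sup>(f)</sup>*‖ ≤ *c* } ,

with edges kept only when *w<sub>ij</sub>* ≥ *p<sub>crit</sub>* (default
20%). The package computes the two fundamental PSN properties — **hubs**
(nodes of degree ≥ 3) and **connected components** (clusters of linked
nodes, ranked by size) — and attaches a leave-block-out **jackknife
standard error** to each of them:

&nbsp;&nbsp;&nbsp;&nbsp;SE<sub>jack</sub> = { (*n*−1)/*n* · Σ<sub>i</sub> (θ̂<sub>(i)</sub> − θ̂<sub>(.)</sub>)² }<sup>1/2</sup> ,

where the *n* = 10 resampled trajectories each discard one contiguous 10%
block of frames. A cutoff scan over 4.0–6.0 Å characterizes the
fragmentation-to-percolation behaviour that makes the choice of cutoff
critical: too short and the network is edgeless and fragmented, too long
and every residue fuses into one cluster.

Seeded synthetic generators — contact schedules with exactly known
persistence, and protein-density compact chains — make every stage
testable without any trajectory data.

## Worked example

```r
library(PSNet)

# A protein-like synthetic ensemble: 50 residues, 100 frames
ens <- generateCompactChain(50, 100, seed = 1)
ens
#> StructuralEnsemble: 50 atoms, 50 residues, 100 frames

res <- runScan(ens, scanConfig())   # cutoffs 4.0-6.0 A, p_crit 20%, n_jack 10
scanSummary(res)
#>   cutoff n_edges n_hubs max_hub_degree n_components n_non_singleton fraction_largest
#> 1    4.0      16      2              3           34               8             0.10
#> 2    4.5      32      8              4           19               5             0.28
#> 3    5.0      79     30              6            2               2             0.96
#> 4    5.5     118     47              8            1               1             1.00
#> 5    6.0     140     50             10            1               1             1.00
```

Reading the table: at 4.0 Å the network is almost empty (2 hubs, largest
cluster holding 10% of the nodes — the fragmented regime), while from
5.0 Å on a single dominant component holds ≥96% of the nodes and a
substantial hub population appears, with degrees inside the sterically
allowed 3–10 range. The percolation transition of this ensemble sits
between 4.5 and 5.0 Å.

Per-cutoff detail, with jackknife error bars:

```r
pc5 <- cutoffResult(res, 5.0)
pc5$hubs
#> HubTable: 30 hubs (min degree 3 )
#>   degree: 3 4 5 6
#>   count:  10 10 6 4

head(estimates(pc5$jackknife)[, 1:5], 5)
#>              observable full_value theta_dot       se  n
#> 1    hub_count_degree_3         10       9.2 4.983974 10
#> 2    hub_count_degree_4         10      10.8 3.498571 10
#> 3    hub_count_degree_5          6       6.1 3.661967 10
#> 4    hub_count_degree_6          4       3.3 3.562303 10
#> 5 component_size_rank_1         48      48.5 4.695743 10

jackknifeSE(c(2, 4, 6))
#> [1] 2.309401
```

`writeReport(res, "outdir")` writes per-cutoff edge lists (TSV), hub /
component / jackknife tables (CSV) and a machine-readable `summary.json`;
re-running on the same input is byte-identical. Real ensembles enter
through `readEnsemble("traj.pdb")` (multi-model PDB) or
`readEnsemble("traj.dcd", topology = "top.pdb")`, and the individual
stages (`selectSideChains()`, `computeComSeries()`,
`computePersistence()`, `buildGraph()`, `findHubs()`,
`connectedComponents()`, `jackknifeObservables()`) are exported for
step-by-step use. A thin command-line front end with `analyze`, `scan`,
`jackknife` and `fixtures` verbs lives at `inst/scripts/psn-cli.R`.

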