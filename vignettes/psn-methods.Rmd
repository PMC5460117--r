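---
title: "Contact-based protein structure networks: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact-based protein structure networks: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PSNet)
```

## The model

A Protein Structure Network (PSN) abstracts a protein as a graph: residues
are nodes and residue–residue contacts are edges. PSNet implements the
side-chain contact variant used widely in PSN-MD work: the representative
point of each residue is the mass-weighted center of its side-chain atoms
(the COM), a frame-level contact exists when two COMs lie within a distance
cutoff, and the edge weight over a structural ensemble is the *persistence*
(or occurrence) of the contact — the fraction of frames in which the pair is
in contact, expressed as a percentage. Edges with persistence below a
critical threshold `p_crit` are discarded as noise.

Formally, for nodes $i, j$ with COM positions $r_i^{(f)}, r_j^{(f)}$ in frame
$f = 1 \dots F$ and cutoff $c$:

$$w_{ij} = \frac{100}{F}\,\#\{f : \lVert r_i^{(f)} - r_j^{(f)} \rVert \le c\},
\qquad (i,j) \in E \iff w_{ij} \ge p_{crit} \text{ and } w_{ij} > 0.$$

Glycine has no side-chain heavy atom, so it cannot carry a side-chain COM
and is excluded from the node set. Two network properties summarize the
topology:

* **Hubs** — nodes with degree at least 3. Steric packing limits residue
  degrees to roughly 3–10, and the hub census is a sensitive probe of
  whether a cutoff is long enough to capture the contact fabric of the fold.
* **Connected components** ("clusters") — maximal sets of mutually
  reachable nodes, ranked by size. A cutoff that is too short fragments the
  network into many small clusters; one that is too long fuses everything
  into a single component. The transition between the two regimes happens
  within the 4–6 Å window for side-chain COM contacts, which is why the
  default cutoff grid covers exactly that range in 0.5 Å steps.

## Statistical error: jackknife over trajectory blocks

Network observables computed from a finite ensemble carry sampling error.
PSNet quantifies it with leave-block-out jackknife resampling: with $n$
subsets (default 10), subset $i$ discards the $i$-th contiguous block of
$\lfloor F/n \rfloor$ frames, so each subset retains 90% of the frames at
the default $n$. Discarded blocks are disjoint and tile the trajectory;
when $F$ is not a multiple of $n$ the remainder frames at the tail are kept
in every subset (a choice we document rather than inherit: the alternative —
spreading the remainder over blocks — makes block sizes unequal and buys
nothing for error estimation).

For an observable with per-subset estimates $\hat\theta_{(i)}$ and mean
$\hat\theta_{(.)} = \tfrac1n \sum_i \hat\theta_{(i)}$, the standard error is

$$SE_{jack} = \left\{ \frac{n-1}{n} \sum_{i=1}^{n}
  \left(\hat\theta_{(i)} - \hat\theta_{(.)}\right)^2 \right\}^{1/2}.$$

The observables tracked are the ones a cutoff benchmark needs: the hub
count at each degree (from the hub threshold up to the largest degree seen
in any subset) and the size of the $k$-th largest component for
$k = 1 \dots 5$. Components are matched across subsets by **size rank**,
not by member identity: rank matching is the only deterministic pairing
that needs no overlap heuristics, at the cost that a rank can change
identity between subsets near a percolation transition — error bars there
describe the rank's size, not one particular cluster. Set-valued,
residue-level comparisons (which residues moved between clusters) are
available from the per-subset membership tables written by the report
writer; they have no standard error in the formula above.

An observable absent from a subset — no hub of degree 5, fewer than $k$
components — contributes $\hat\theta_{(i)} = 0$, the size or count of an
empty set.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `cutoffs` | 4.0–6.0 step 0.5 | Å | COM–COM contact distance grid |
| `pCrit` | 20 | % | minimum persistence for an edge |
| `nSubsets` | 10 | — | jackknife subsets (block = 10% of frames) |
| `minHubDegree` | 3 | — | hub definition |
| `topK` | 5 | — | component ranks reported |
| `excludedResnames` | GLY | — | residues never used as nodes |
| `minSeqSeparation` | 0 | residues | optional near-diagonal contact filter |
| `frameStride` | 1 | frames | input subsampling |

Three numerical conventions worth knowing, since other PSN software may
differ:

* the distance test is **inclusive** (`distance <= cutoff`), and so is the
  persistence filter (`weight >= pCrit`): `p_crit = 20` reads "in contact in
  at least 20% of frames". Anyone comparing bit-exactly against software
  with strict inequalities should expect differences for pairs sitting
  exactly at a threshold;
* sequence-adjacent pairs are **not** excluded by default — the side-chain
  COMs of neighbours in sequence are genuine spatial contacts under this
  edge definition. `minSeqSeparation` exists for users who want the
  backbone-neighbour contacts removed;
* distances are plain Euclidean: inputs are assumed whole-molecule, with
  periodic-boundary artifacts already removed upstream.

Hydrogens are included in the COM when the input has them; mass weighting
makes their contribution small (≈1% of a carbon), so all-atom and
united-atom ensembles can be analyzed without special-casing. Masses
default to standard element masses; force-field-specific tables are a
user-supplied override via `readMassTable()`, whose effect on COMs is at
the same sub-percent scale.

Component ranks break size ties deterministically by the smallest member's
`(chain, resid, icode)`. This makes cluster IDs reproducible across runs,
which rank-matched jackknife errors require.

## The synthetic generators, and what they do and do not show

No MD engine ships with this package; two seeded generators produce
ensembles whose network-level ground truth is known exactly.

**Schedule ensembles** (`contactSchedule()` + `generateScheduleEnsemble()`)
program, pair by pair, which frames a contact exists in. Pairs sit at
`dIn` in contact frames and at least `dOut` apart otherwise, so downstream
persistence equals the programmed fraction $k/N$ with zero floating error.
Only 3D-embeddable contact families are accepted (disjoint pairs, chains,
stars), and the generator re-measures every realized distance before
returning, erroring out rather than emitting geometry that violates its
schedule. Keeping `dIn` and `dOut` at least 1 Å away from every scanned
cutoff makes the fixtures immune to the 3-decimal rounding of PDB output.
Each pseudo-residue carries a single CB atom, so these fixtures exercise
the persistence and graph stages non-trivially but the COM stage only
trivially; multi-atom COM arithmetic is tested separately on hand-built
residues.

**Compact chains** (`generateCompactChain()`) emulate the packing of
side-chain COMs in a globular protein: a self-avoiding random walk with
5.5 Å sequential spacing, a 4.2 Å excluded-volume floor between
non-adjacent residues, confinement to a sphere of 135 Å³ per residue
(≈11.7 Å radius for 50 residues), and 0.5 Å per-frame Gaussian jitter
standing in for thermal motion. The sequential spacing deserves a note:
we deliberately use the typical distance between *side-chain COMs* of
sequence neighbours (≈5–6 Å), not the 3.8 Å CA–CA virtual bond. A 3.8 Å
backbone-spaced chain of COM pseudo-atoms would be permanently connected
end to end at every cutoff in the grid, hard-wiring a chain-spanning
component and erasing the fragmentation regime the scan exists to expose.
With these defaults the default grid brackets the percolation transition:
at 4.0 Å the network is nearly edgeless and fully fragmented, by 6.0 Å a
single component holds every node, and the switch happens near 5 Å.

What passing tests on these fixtures shows: the persistence arithmetic,
filtering, graph properties, resampling accounting and report plumbing are
exact and deterministic. What they do not show: anything about real
protein energetics or force-field behaviour. The compact chain has
protein-like *density* but no secondary structure, no correlated side-chain
motions, no rotamer jumps — conclusions about a specific protein still
require a real ensemble from MD or experiment.

## Problem sizes and degenerate inputs

The test suite and the acceptance script run on 50-residue, 100-frame
ensembles — large enough to exhibit the full fragmentation-to-percolation
range over the default grid, small enough that a complete 5-cutoff scan
with 10 jackknife subsets takes about a second. The implementation computes
the per-frame COM distance array once per ensemble and reuses it across
cutoffs and subsets, so a grid scan costs little more than a single-cutoff
run and is guaranteed to equal the standalone result slice for slice.

Degenerate inputs behave predictably: a single-frame ensemble gives 0/1
persistence values; an identical-frame ensemble gives zero jackknife SE for
every observable; an ensemble with fewer frames than subsets is rejected;
residues reduced to backbone atoms are excluded from the node set with a
logged reason, and an input with no usable side chains at all is a fatal
error rather than an empty analysis.

## Known limitations

* No XTC/TRR reader: binary input is limited to DCD plus a PDB topology;
  other formats should be converted upstream.
* No alternative edge chemistry (hydrogen bonds, hydrophobic-cluster or
  energy-based networks) and no path/centrality analysis: the scope is the
  contact-persistence network and its two fundamental properties.
* The jackknife assumes approximately exchangeable blocks; strongly
  autocorrelated trajectories with slow transitions violate this, and the
  SE then underestimates the true sampling error. No
  statistical-inefficiency correction is applied.
* Rank-matched component errors near a percolation transition mix cluster
  identities, as discussed above.
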