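---
title: "Methods: particle line notation, tube geometries and box setup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: particle line notation, tube geometries and box setup}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spices)
```

## The representation

Mesoscopic simulation techniques such as Dissipative Particle Dynamics treat
a molecule as a graph of coarse-grained fragment particles joined by harmonic
springs. `spices` encodes such graphs as a line notation: particle names
joined by `-`, branches in `(-...)` bonding to the preceding particle, ring
closures as paired `[k]` labels, parts separated by `.`, plus per-particle
backbone labels (`'12'`) and at most one `[START]`/`[END]` tag pair per part.
The parser produces a plain node/bond graph; particles are opaque labels and
no chemistry-aware perception (valence, aromaticity, charge, chirality) is
attempted — fragments differing in charge or stereochemistry are distinct
particle names by design.

Two deliberate consequences of the model's assumptions run through the whole
package:

* **The notation is not canonically unique.** Serialization therefore makes
  no attempt at canonicalization; the contract is that re-parsing the output
  gives a graph isomorphic to the input, with names, backbone labels, tags
  and part count preserved.
* **Particles may coincide in space.** Soft mesoscopic potentials tolerate
  exact overlap, so the tube construction collapses whole side chains onto
  single main-chain positions instead of generating extended conformations.

### Grammar decisions

The surface dialect was fixed here (a letter-initial alphanumeric particle
token; an explicit `-` between adjacent particles, required also for the
first particle of a branch; positive-integer ring labels appearing exactly
twice per part, reusable after closure; a positive-integer repeat prefix
`6Et` expanding to a linear chain). Whitespace and non-ASCII bytes are
rejected so that error offsets are unambiguous; all reported offsets are
0-based character positions into the input. A repeat group cannot carry a
backbone label or tag — labels are per-occurrence identities, and a repeat
group has no single occurrence to attach them to; a ring closure after a
repeat group is allowed and attaches to the last expanded copy, which is a
positional rather than identity attachment. The validator recovers after
each error and reports every problem it can find; `parse_spices()` raises on
the first. Node indices in the R API are 1-based, as is idiomatic in R.

## Topology queries

Particle frequencies, neighbor shells (exact graph-distance classes computed
by breadth-first search) and part extraction are direct graph operations.
The interesting algorithm is the main-chain search used for tube building:

1. From the first particle of the notation, a depth-first search finds the
   maximum-distant particle *A* (distance along the DFS tree).
2. A second DFS from *A* finds the maximum-distant particle *B*; the
   recorded *A*→*B* tree path is the chain.

On acyclic molecules the two sweeps provably find a true longest path; on
cyclic molecules the result may be shorter than optimal, which is accepted:
for small fragment molecules the alternative tubes are similar enough that
simulations converge to the same answers. Determinism is pinned down by two
tie-break rules: DFS explores neighbors in ascending node index, and the
maximum-distance node with the lowest index wins. An untagged chain has two
valid orientations; we return the one starting at the lower-indexed
endpoint.

With a `[START]`/`[END]` pair the chain must run from the tagged head to the
tagged tail. We enumerate simple paths from START by exhaustive backtracking
DFS and keep the longest reaching END (first found among ties). The
enumeration is capped at a state budget (`max_states`, default 10^4 visited
states, ample for fragment-scale molecules); past the budget the best
complete path found so far is returned, and if none has been completed yet
the search simply continues until the first one is. This fallback was chosen
over a START/END-constrained double sweep because it is simpler, always
returns a valid oriented simple path, and concedes optimality only on large
cyclic molecules — exactly where the double sweep concedes it too. A part
with only one of the two tags falls back to the untagged search: orientation
needs the pair.

## The linear 3D tube

`map_molecule_to_line()` places the `m` main-chain particles on the caller's
start→end line. All geometry parameters are in box-length units. With line
length `L` and requested bond length `b` (default 1), the realized spacing is

* `b` when `(m-1)·b ≤ L` — the tube then ends at or short of the end point;
* `L/(m-1)` otherwise — a uniform squeeze.

The first main-chain particle sits exactly (bit-exactly, not merely within
tolerance) at the start point, which is what lets a compartment editor
position head groups without pre-checking lengths. Every side-chain particle
takes the exact position of its *host*: the main-chain particle at minimum
bond-count distance, ties broken toward the lower chain position index.
Graph distance is the only metric available before positions exist, and a
single multi-source BFS seeded with the chain in position order yields both
the minimum distance and that tie-break at once. Nested side branches
collapse directly onto their nearest main-chain particle (for a branch
hanging off one chain particle, every choice coincides anyway).

Degenerate inputs: a single-particle molecule is placed at the start with an
effective bond length reported as 0; equal start and end points are rejected
when the `line_spec` is built, since no direction exists. Main-chain
collinearity holds to within 1e-9 relative tolerance (verified in tests);
side-chain collapse is exact by construction because host positions are
copied, not recomputed.

## Box population and the record table

`random_lines()` draws uniform start points and uniform-on-sphere
orientations (normalized Gaussian triples), resampling the orientation up to
1000 times until the end point is inside the box; `bilayer_lines()` builds
two mirrored leaflets of lines parallel to the chosen normal axis, running
from the midplane-distal side toward the midplane so START-tagged heads face
outward. Seeding uses one root seed with a per-line substream derived by
counter offset, so line *i* is identical whether 1 or 50,000 lines are
generated — this is what makes population output byte-reproducible.

`project_population()` computes the molecule's main chain, collapse hosts
and offset pattern once and reuses them across all lines, so a population of
50,000 DMPC molecules (800,000 records) projects in a few seconds on one
CPU. Bonds are coded as signed record-index offsets, intra-molecular only;
molecules are independent bonded blocks and no inter-molecular bonds are
emitted. Force assignment is deliberately kept out of the notation: a
backbone label is only an indirection key, resolved against a user-supplied
label→index map at projection time (strict by default — a molecule label
missing from a non-empty map is an error — permissive on request). The
tabular ASCII dialect (documented in `write_box_table()`) prints coordinates
at fixed 6 decimals, which makes write→read→write a byte fixpoint; with a
box given, coordinates are clamped inclusively into `[0, extent]` on write.

## What the random-molecule generator emulates — and what it does not

`random_molecule()` grows a random tree (chain-biased, with a branching
probability), optionally adds ring-closure bonds, labels and a tag pair, and
emits the graph through the serializer, so its output is valid by
construction with an exact particle count. It emulates the *topological*
variety of fragment molecules — branching, small cycles, labels, tags —
which is what the parser, the chain search and the record table are
sensitive to. It does not emulate chemical plausibility: no valence limits,
no realistic name/fragment statistics, no correlation between labels and
ring membership, and no multi-part aggregates. Passing property tests
therefore demonstrate correctness of the graph machinery on arbitrary
topologies, not that any particular fragmentation scheme is chemically
sensible — fragmentation design remains the modeler's craft. The bundled
sterol-like fixture is likewise a structural analog (17 labeled particles,
two fused cycles), not a verbatim fragmentation of cholesterol.

## Problem sizes and test design

The suite exercises: round-trip isomorphism on 500 generated molecules of up
to 20 particles (checked against an independent VF2 oracle), double-sweep
optimality against brute-force longest paths on 200 random trees of up to 14
particles, neighbor shells against an independent BFS-distance oracle,
offset closure on generated population tables, a 50,000-molecule DMPC
projection (800,000 records), and byte-level determinism of seeded runs.
These sizes keep the full suite around half a minute while covering every
code path; all randomized tests use fixed seeds.

## Known limitations

* The linear tube is a *start* geometry, not a conformation. For large
  cross-linked polymers a straight collapsed tube is questionable in
  principle; structure-aware converters (e.g. from PDB coordinates) would be
  the right tool there and are out of scope.
* On cyclic molecules the untagged chain search is heuristic, and different
  but equally valid notations of the same molecule may give different tubes.
* DPD force-field parametrization, length/time-scale and concentration
  calculators, and any coupling to a simulation kernel are out of scope; the
  package stops at the kernel's input table.
* The interactive graph viewer of the original tooling is replaced by static
  DOT/GraphML export consumable by standard graph tools — the algorithmic
  content is the model, not the widget.
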