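# spices

Particle-based molecular line notation and simulation-box start geometries
for mesoscopic simulation.

Mesoscopic techniques such as Dissipative Particle Dynamics (DPD) describe
molecules not atom by atom but as graphs of coarse-grained "molecular
fragment" particles (beads of roughly 100 Da) bonded by harmonic springs.
Simulation kernels consume large tabular ASCII files — one line per particle
with its x/y/z position, signed line offsets to its bonded partners, and a
force index — and writing those files by hand is tedious and error-prone.
`spices` is for the modeler preparing such simulations: it provides a
SMILES-derived line notation for particle graphs, safeguarded parsing with
positional error diagnostics, topology queries, conversion of a topology
into a linear 3D tube start geometry, and the population of a simulation box
with many such tubes, written out in kernel-ready tabular form.

## The notation

A molecule is a string of particle names joined by bonds. The grammar
implemented here (this package's normative dialect) is:

| construct | syntax | example |
|---|---|---|
| particle | letter, then letters/digits | `Et`, `MeAc`, `TriMeNP` |
| bond | `-` between adjacent particles | `Et-Et` |
| branch | `(-...)` bonding to the preceding particle | `DMPN(-MeAc-6Et)` |
| ring closure | `[k]`, a positive integer appearing exactly twice per part | `A[1]-B-C-D[1]` |
| backbone label | `'text'` after a particle name | `Me'12'` |
| orientation tags | `[START]` / `[END]`, at most one each per part | `TriMeNP[START]` |
| repeat prefix | `nX` = n copies of particle `X` chained linearly | `6Et` |
| part separator | `.` between independent parts | `A-B.C` |

Whitespace and non-ASCII characters are rejected; a repeat group may not
carry a backbone label or tag. Charges and chirality are deliberately not
part of the notation: differently charged or enantiomeric fragments are
simply different particles. The notation is not canonically unique, and the
package never canonicalizes.

## Core algorithms

* **Longest chain (double DFS sweep).** From the first particle of the
  notation a depth-first search finds the maximum-distant particle *A*; a
  second DFS from *A* finds the maximum-distant particle *B*, and the
  recorded *A*→*B* path becomes the tube axis. On acyclic molecules this is
  a true longest path; on cyclic molecules it may not be, which is accepted.
  With a `[START]`/`[END]` tag pair the longest oriented simple path between
  the tagged particles is used instead.
* **Linear 3D tube.** The `m` main-chain particles are lined up from the
  line's start point with spacing `min(bond_length, L/(m-1))` where `L` is
  the line length — i.e. the tube is uniformly squeezed when the line is too
  short and ends short of the line's end when it is too long. Every
  side-chain particle is collapsed onto the exact position of its nearest
  (by bond count) main-chain particle. Coinciding particles are fine under
  the soft potentials of mesoscopic simulation.
* **Box population.** `random_lines()` and `bilayer_lines()` generate seeded
  line placements (uniform positions/orientations, or two mirrored leaflets
  with head groups facing outward); `project_population()` maps one molecule
  onto every line and emits the concatenated record blocks.

## Worked example

The bundled DMPC phospholipid fixture decomposes the lipid into 16
particles: a choline head (`TriMeNP`, START-tagged), a phosphate/glycerol
particle (`DMPN`), and two ester+tail arms (`MeAc` + six `Et` each), the
second ending in the END tag.

```r
library(spices)

mol <- parse_spices(fixture_dmpc())
mol
#> <spices_molecule: 16 particles, 15 bonds, 1 part>
#>   notation: TriMeNP[START]-DMPN(-MeAc-6Et)-MeAc-5Et-Et[END]
#>   particles: Et x12, MeAc x2, DMPN x1, TriMeNP x1

longest_chain_oriented(mol)
#> <chain_path: 9 particles, oriented (START -> END)>
#>   1 - 2 - 10 - 11 - 12 - 13 - 14 - 15 - 16

mp <- map_molecule_to_line(mol, line_spec(c(0, 0, 0), c(10, 0, 0), bond_length = 1))
particle_positions_and_connections(mol, mp)
#> <box_record_table: 16 records>
#>       name x y z bond_offsets force_index
#> 1  TriMeNP 0 0 0           +1           0
#> 2     DMPN 1 0 0     -1,+1,+8           0
#> 3     MeAc 1 0 0        -1,+1           0
#> 4       Et 1 0 0        -1,+1           0
#> ...
```

The 9-particle main chain runs head to tail-end; the whole side arm (one
`MeAc` and six `Et`) collapses onto the `DMPN` particle at x = 1, so that
second main-chain position holds 8 particles with the exact same position.
Record 2's offsets `-1,+1,+8` say: bonded to the records one before it
(`TriMeNP`), one after it (the side-chain `MeAc`) and eight after it (the
main-chain `MeAc`).

Validation never raises — problems come back as data with 0-based offsets:

```r
validate_spices("A(-B-C")
#> <parse_report: invalid, 1 error>
#>   offset 1: unclosed branch
```

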