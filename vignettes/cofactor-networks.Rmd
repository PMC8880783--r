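---
title: "Cofactor networks and electron-transfer pathways: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cofactor networks and electron-transfer pathways: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cofanet)
```

## The analysis

Electron-bifurcating flavoenzymes split pairs of electrons at a flavin
onto a high-potential and a low-potential pathway. In the bifurcating
NiFe-hydrogenase family, the machinery is a heteropentamer carrying a
catalytic NiFe site, an FMN/NAD pocket, and a constellation of twelve
iron-sulfur clusters (eight [4Fe-4S], four [2Fe-2S]) named A1-A5 (HydA),
B1-B5 (HydB), C1 (HydC) and S1 (proximal to the NiFe site). Which of
these centers can pass electrons to which is, to first order, a question
of distance: productive single-step tunneling between protein-bound redox
centers is bounded at roughly 14 Å between cofactor edges. The package
turns an atomic model into that distance picture and the graph-level
conclusions that follow from it: which centers form chains, which sit at
branch points ("Y"-shaped cluster arrangements), which arms are dead
ends, and how conformational states open and close specific gaps.

## Distance metrics

Two metrics are computed for every cofactor pair:

* **edge-to-edge** (side-to-side): the minimum distance over all
  non-hydrogen atom pairs of the two cofactors. This is the operative
  quantity for tunneling feasibility and is what the 14 Å threshold is
  applied to.
* **center-to-center**: the distance between geometric centers, reported
  as the conventional companion figure.

For flavins and nicotinamide cofactors the center set is the conjugated
ring system (isoalloxazine, nicotinamide) rather than the full molecule,
since the ring is the redox-active moiety; for FeS clusters and the NiFe
pair it is all non-hydrogen member atoms. Hydrogens are excluded by
default everywhere (models at typical cryo-EM resolutions carry no
reliable hydrogen positions); a flag re-includes them.

## The transfer graph and its classification

`build_et_graph()` places an undirected edge wherever the edge-to-edge
distance is at or below the threshold `tau` (default 14 Å). The graph is
undirected because the chemistry is reversible (bifurcation and
confurcation run over the same relays); directionality is an
interpretation, not a geometric property. `topology()` classifies nodes:
degree ≥ 3 is a branch point, a degree-1 node not designated a terminal
is a dead end. *Terminals* are the physical entry/exit points of the
network — the catalytic site, substrate-binding cofactors, and any
cluster proposed to hand electrons to an external partner.

Two path analyses are provided:

* `enumerate_paths()` lists all simple paths between two labels. Paths
  may start or end at a terminal but never relay *through* one: an
  electron path from the flavin to the catalytic site cannot detour via
  the NAD substrate stacked on the flavin face. This matters in
  practice — NAD necessarily lies within 14 Å of the flavin-proximal
  cluster (it sits 3.4 Å above the isoalloxazine, which is itself ~6 Å
  from that cluster), so without the rule every flavin-origin path would
  have a spurious NAD-mediated twin.
* `minimax_path()` finds the route minimizing the largest single step,
  with no threshold at all. This supports reasoning about gaps *slightly
  outside* the nominal range: a 17 Å bottleneck is not a viable relay as
  it stands, but identifies the step a conformational change would have
  to shorten. The bottleneck value is obtained from a minimum spanning
  tree (the largest edge on the tree path between two nodes is the
  minimax value); ties are resolved toward fewer nodes, then
  lexicographic label order, so results are deterministic.

## Conformational-state comparison

`superpose()` is a least-squares (Kabsch) fit over atoms paired by
(chain, residue number, insertion code, atom name) identity; the
rotation is constrained proper (determinant +1), so mirror relationships
surface as nonzero RMSD rather than an improper transform.
`domain_rotation()` superposes two states on a user-chosen *core*
selection, then fits the residual motion of a *domain* selection and
reports it as a screw motion: angle θ = arccos((trace(R) − 1)/2) in
[0°, 180°], unit axis, and the translation component along the axis. The
axis sign is chosen to make that translation non-negative (first nonzero
axis component positive in the degenerate case), which removes the
axis-sign ambiguity and makes θ symmetric between the states. Core and
domain boundaries are inputs, not inferences: the package ships defaults
only for its own fixtures, because domain definitions on real models are
an interpretive choice.

`compare_states()` reports, per cofactor pair, the edge distance in each
state, the delta, and a `crossed_threshold` flag set when the pair is
within `tau` in exactly one state — the distance-gating summary used to
contrast a bifurcation-ready and a post-bifurcation conformation.

## The synthetic-structure generator

Real deposited models of this enzyme family cannot be bundled, and
cryo-EM reconstruction is far outside desk scale, so every pipeline
stage is exercised on generated structures whose geometry is controlled
to 0.05 Å. `make_constellation()` places idealized cofactor templates
(cubane Fe4S4 with 2.7 Å Fe-Fe; rhombic Fe2S2; planar tricyclic
isoalloxazine with 1.4 Å aromatic bonds; nicotinamide ring; Ni-Fe pair
at 2.6 Å) so that every *constrained* pair's edge-to-edge distance hits
its target and every *unconstrained* pair stays beyond a repulsion
floor. The solver is a two-stage damped stress iteration: centers are
first relaxed with reach-corrected spring targets, then the true
edge-to-edge distances (which depend on each template's seeded random
orientation) are re-measured and the two bodies of each violated
constraint slide along their center line by half the signed error.
Orientation draws that admit no solution (e.g. a ring whose span is
needed along a particular direction but points elsewhere) are retried
with fresh seeded orientations; persistent failure raises an
infeasibility error listing the constraint set. Output is bit-for-bit
reproducible given (spec, seed), and the caller's RNG stream is left
untouched.

`make_hydabcsl_fixture()` encodes the enzyme's reported cofactor constellation
in three states. The parameters below are the study conditions; the
distances marked *measured* are the experimentally reported figures, the rest are
fixture parameters chosen once:

| pair | apo | BR | PB | status |
|------|-----|-----|-----|--------|
| FMN-B1 | — | 6.0 | 6.0 | measured |
| C1-FMN | — | 15.5 | 13.0 | BR measured; PB fixture parameter |
| C1-B2 | 19.0 | 19.0 | 13.4 | apo/PB measured; BR carried over from apo |
| B2-B3 | 18.0 | 18.0 | 17.0 | apo/PB measured; BR carried over |
| C1-B3 | — | — | 17.4 | measured |
| B5-C1 | 11.0 | 11.0 | 11.0 | measured (apo) |
| B1-C1 | 22.5 | 22.5 | 22.5 | encodes "beyond 22" |
| chain steps (B1-A1, A1-A2, A2-A3, A3-S1, S1-NiFe, A2-A4, A4-A5, B3-B4) | 11.0 | 11.0 | 11.0 | fixture parameter |
| NAD C4 to FMN N5 | — | 4.2 | 4.2 | measured (exact, by construction) |

Rationale for the two choices that were genuinely open:

* **PB C1-FMN = 13.0 Å.** No figure is reported for this pair in the
  post-bifurcation state. The bifurcation-competent flavin-cluster
  geometry is inferred to be ~12 Å, and the C1 hub's three-armed
  connectivity (to B2, B5 and the flavin) is the defining feature of the
  second "Y". Setting the pair just inside the threshold realizes that
  connectivity while staying geometrically compatible with the B1-C1 >
  22 Å exclusion (12 Å would make the triangle nearly degenerate).
* **Chain steps at 11.0 Å.** Only chain *membership* is reported for
  these steps, not lengths; 11 Å is a typical relay spacing, safely
  inside the threshold, and far enough from it that the 0.05 Å solver
  tolerance can never flip an edge.

The repulsion floor is 18 Å: above the 14 Å threshold so no incidental
contact creates an edge, and above the largest encoded gap (17.4 Å) so
bottleneck-path reasoning is decided by the encoded distances, not by
where unconstrained bodies happen to land. NAD is exempted from the
floor and rides rigidly with FMN: its 4.2 Å C4-N5 contact is an
atom-pair constraint, not a cluster gap, so it is built by construction
(stacked 3.4 Å above the ring plane with the lateral offset that makes
the contact exact) rather than solved. The dimer option places a second
pentamer with all inter-pentamer cofactor distances beyond 40 Å,
reflecting the electric insulation of the two halves of the physiological
dimer.

**What the generator does and does not emulate.** It reproduces the
*distance geometry* of the cofactor constellation — which is the only
input the network analysis consumes — plus minimal coordination-shell
fragments when requested (Sγ-Fe 2.3 Å, Nε-Fe 2.2 Å). It does not build
protein folds, realistic cofactor environments, crystallographic
disorder, or experimental coordinate error. Passing tests therefore
demonstrate that the *analysis* is correct on models whose ground truth
is known exactly; they do not validate cofactor detection against the
quirks of real deposited files beyond the format features the parsers
are tested on (fixed columns, blank element fields, altlocs,
multi-character identifiers in mmCIF).

## Numerical choices and degenerate inputs

* Distances are computed in full double precision and reported at 0.1 Å
  where a display precision is called for.
* Edge-distance ties between atom pairs resolve to the first pair in
  source atom order.
* Altlocs collapse to the highest-occupancy conformer (ties → altloc A);
  multi-model files default to model 1 with an explicit override.
* `stoichiometry()` reports an Fe:Ni ratio of `NA` when no Ni is present
  (undefined, not an error); a Ni atom with no pairable Fe within 3.5 Å
  becomes a `CUSTOM` cofactor with a warning, not a failure.
* Kabsch fits reject pairings with fewer than 3 atoms or collinear
  geometry (rank error) rather than returning an underdetermined
  transform; θ extraction clamps the trace into [-1, 3] against roundoff.
* An empty structure is a valid input throughout: empty inventory,
  zero-edge graph, a report that says so.

## Problem sizes

The test suite runs entirely on generated data: fixtures of 13-17
cofactors (82-164 atoms), property sweeps over 100 random placement
specs, path-enumeration and minimax checks against brute-force oracles
on random instances of up to 8 nodes, and noise-recovery studies on
two-domain structures of a few hundred atoms. These sizes were chosen to
make every brute-force oracle exact and the whole suite fast; all
algorithms scale comfortably to real single-complex models (hundreds of
residues, tens of cofactors).

## Known limitations

* No tunneling-rate or driving-force model (Moser-Dutton style): the
  analysis is purely geometric, by design.
* No oxidation-state or protonation logic, no heme or molybdopterin
  support (extensible via `CUSTOM` dictionary entries).
* Domain rotations on real conformational ensembles depend on the chosen
  core; numerical agreement with figures derived from map-space
  variability analyses is not promised — construction-based recovery is
  the validated surface.
* mmCIF writing emits a minimal `atom_site` loop (sufficient for
  round-tripping coordinates and identities), not a full metadata
  dictionary.
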