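---
title: "Profiling fragment binding: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling fragment binding: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragbind)
```

## The procedure

`fragbind` compares how different proteins hydrogen-bond one rigid ligand
fragment. The pipeline rests on a single modelling idea: because the
fragment (adenine by default) is rigid and planar, superposing all
complexes on the fragment puts every protein's hydrogen-bonding atoms into
one common coordinate frame, where "the same interaction in two proteins"
becomes a plain geometric statement about two points being close.

For each input complex the stages are:

1. **Fragment detection.** The ligand's bond graph is inferred from
   interatomic distances (bonded when d < r₁ + r₂ + 0.4 Å over covalent
   radii; HETATM connectivity records are too unreliable to require).
   Fragment copies are all element-labeled subgraph isomorphisms of the
   fragment graph into the ligand graph (VF2), deduplicated per atom set.
   Adenine's ten heavy atoms have no nontrivial automorphism, so the
   deduplication is a no-op for the default fragment; it is kept for
   generality.
2. **Superposition.** A least-squares rigid fit (Kabsch, via SVD) maps the
   instance onto the fragment's canonical reference coordinates over all
   ten mapped atoms, unweighted. Reflections are rejected (det = +1).
3. **Interaction extraction.** Hydrogen bonds are detected with
   hydrogen-free, heavy-atom criteria (below); each partner is assigned a
   binding edge from its position in the canonical frame; water bridges
   through a single ordered water are recorded with both legs. The
   resulting *interaction site* is the set of partner points in the
   canonical frame — for mediated bonds the bridging-water oxygen, which
   is what superposed site displays show.
4. **Motif classification and networks**, described below.

### The canonical frame

No convention for the fragment frame exists in the field, so the package
fixes one so that all modules and fixtures agree bit-for-bit: the centroid
of the nine ring atoms at the origin, the ring plane as *xy*, the C4–C5
bond midpoint on +*x*, and N1 at positive *y* (which fixes the
handedness). The shipped reference coordinates are an MMFF94-optimized
adenine projected to exact planarity; bond lengths sit at standard purine
values (N1–C2 = 1.35 Å).

## Hydrogen-bond model

Most deposited structures lack hydrogens, so the criteria use heavy atoms
only, in the spirit of heavy-atom polar-contact detectors:

| parameter | default | unit | rationale |
|---|---|---|---|
| `maxDaDistance` | 3.5 | Å | between the 3.2 Å (strict) and 3.9 Å (lax) presets used for sensitivity analysis; the three produce nested bond sets |
| `minAntecedentAngle` | 90 | ° | X–D⋯A ≥ 90° for every covalent neighbor X of the donor rejects partners buried behind it; exact angular cutoffs vary between published tools, so this is deliberately permissive and validated property-wise |
| `waterBridgeMax` | 3.5 | Å | per leg of a fragment–water–protein bridge |
| `includeWeakCh` | off | – | C2/C8 aromatic C–H are weak donors; the interactions of interest are N/O chemistry |
| `includeS` | on | – | Cys/Met sulfur as a weak acceptor; sulfur partners are part of the observed binding repertoire |

Donor/acceptor roles are complementarity-enforced: adenine's only donor is
N6, its acceptors are N1, N3, N7; protein candidates are tabulated by
residue and atom name. Duplicate detections per (fragment atom, partner)
keep the shortest distance; a direct bond beats a water-mediated one to
the same partner; among duplicate mediated bonds the shortest total leg
length wins. Only single-water bridges count — chains of two waters are
bulk solvent.

### Edge assignment at N6

N1, N3 and N7 each sit on exactly one edge. N6 sits between the
Watson–Crick and Hoogsteen edges, and no published rule separates its two
interaction clusters, so the package operationalizes the split: the sp²
amine's two N–H directions lie at ±60° from the C6→N6 bond extension, one
toward N1 and one toward N7; a partner is assigned the edge whose
idealized N–H direction its in-plane projection is closer to. The
decision boundary is then the C6–N6 axis itself, so mirror-image partners
always resolve to opposite edges — a property the tests enforce. Partners
exactly on the axis tie and fall deterministically to Watson–Crick.

## Motif rules

The classic three-position loop motifs are defined here by their two
anchor bonds on the Watson–Crick edge — carbonyl O accepting from N6 and
amide N donating to N1 — with the *direct*/*reverse* distinction carried
purely by the sequence order of the two residues, and the *Asp* motif
replacing the carbonyl with a side-chain O/S of Asp/Glu/Asn/Gln/Ser/Cys
(the Ser/Cys cases flagged as a variant). The source descriptions defer
the exact positional windows to earlier literature, so two
operationalizations are explicit and configurable:

* the two backbone residues must be within 3 positions on the same chain
  (`window = 3`, a loop-proximity constraint);
* when a site satisfies both the Asp and a backbone rule, Asp wins
  (`priority = c("asp", "direct", "reverse")`) — the side-chain
  interaction is the more specific observation.

Two extended variants are recognised: a reverse site with an additional
backbone carbonyl 22–23 residues downstream accepting from N6 on the
Hoogsteen side ("position XV/XVI"), and a single residue whose backbone
carbonyl accepts from N6-Hoogsteen while its amide donates to N7. For the
latter, the literature phrasing lists "amide and carboxyl" against "N6
and N7" ambiguously; read literally it would pair two donors and two
acceptors, which no role-complementary detector can produce, so the
package implements the chemically coherent pairing (carbonyl←N6-H,
amide→N7), which also parallels the reverse motif's carbonyl-to-N6 bond.

## Site similarity and networks

Two sites in the common frame are compared by greedy mutual-nearest-
neighbor matching: candidate pairs are partner points of the same element
category (waters are their own category) within `matchCutoff = 1 Å`; the
globally closest pair matches first. The published similarity notion —
"at least 60 % of the atoms the same" — does not fix the denominator, so
the package uses the larger site (conservative; the quoted two-out-of-
three examples are consistent with equal-size sites). An edge requires
`matchedFraction ≥ 0.6` *and* `partnerRmsd < 0.3 Å` over the matched
pairs; nodes require ≥ 3 hydrogen bonds, the minimum to anchor a rigid
fragment. Both thresholds are monotone: relaxing either can only add
edges, matching the observed sensitivity behaviour (laxer thresholds
connect the network, stricter ones disintegrate it).

Theme-sharing edges require *participation on both endpoints*: a theme (an
annotated 35–200-residue sequence segment) participates in a site when at
least one residue of its range hydrogen-bonds the fragment there.
Participation is judged at residue level — annotations speak of residues,
not atoms. Consensus binding modes of a cluster are the interaction
classes (fragment atom, edge, partner descriptor, mediated flag) present
in at least `minShare` of members; the default 1.0 reports only
interactions shared by every member. Enrichment is plain conditional
arithmetic, fold = P(ligand | theme)/P(ligand), reported with exact
counts.

Determinism is a design goal throughout: components are ordered by size
then lexicographic smallest member, candidate matches break ties on
indices, and every CLI command writes byte-identical output on rerun.

## What the synthetic generator emulates — and what it does not

`generateSite()` builds a minimal complex around the fragment placed at
its reference coordinates: the ligand is adenine plus a carbon cap on N9
standing in for the ribose; partners are pseudo-residues (glycine
backbones, or the side chain a descriptor requires) placed at planted
distances along idealized lone-pair directions, with optional in-plane and
out-of-plane angles; waters implement bridges; the whole complex then gets
a random rigid pose so superposition is exercised for real. Jitter is a
per-residue rigid Gaussian displacement, redrawn (deterministically) until
no inter-residue contact falls below 2 Å. Every generator is a pure
function of (plan, seed).

Family datasets separate binding-site families by a length-4 parity code
over four out-of-plane direction slots (elevations −66°, −22°, +22°, +66°)
at N1, N3, N6 and N7: any two codewords differ in at least two of four
partners, so cross-family sites share at most 2/4 = 50 % of their atoms —
below the 60 % edge criterion — while differing partners sit ≥ 2.17 Å
apart, above both the 1 Å match cutoff and the default 2 Å family
separation. Elevation-only slots were chosen because in-plane rotations at
one ring position lean into the territory of the neighboring position
(N1/N6 are 2.4 Å apart; N3 abuts the N9 substituent) and clash.

The fixtures are deliberately minimal: no folded protein context, no
crystallographic noise model beyond isotropic jitter, no competing ligand
density, no alternate conformations, no aromatic stacking partners.
Passing tests therefore demonstrate the correctness of the geometry,
detection and classification machinery under controlled conditions — not
detector performance on real crystallographic data, where resolution,
protonation ambiguity and modelling errors dominate.

## Numerical choices and degenerate inputs

* Kabsch rejects inputs whose mapped atoms are collinear (second singular
  value < 10⁻⁶ of the first): the rotation about the axis is undefined.
  Planar inputs (rank 2) are fine and are the normal case.
* Rotation validity is enforced at 10⁻⁸ (orthogonality and det = +1).
* Empty sites compare with fraction 0 and rmsd +∞; they can never gain
  network edges.
* Altloc resolution keeps the highest occupancy, ties to altloc "A";
  multi-model files reduce to model 1. Neither policy is stated in the
  source material; both are recorded here as package conventions.
* Author residue numbering (with insertion codes) is used everywhere,
  because theme annotations reference author numbering; ranges are
  1-based and inclusive.
* Planted bond distances are restricted to [2.5, 3.4] Å so fixtures sit
  inside every preset threshold.

## Problem sizes

The shipped test-suite and acceptance script run, by choice, at desk
scale: 100 seeded synthetic sites for the hydrogen-bond recovery sweep, 4
families × 6 members (and 10 × 10 for the large-cluster report) for
network recovery, 10-complex theme fixtures, and a 10⁵-entry corpus for
the enrichment independence check. These sizes keep the full suite under
a minute while exercising every code path; all of them scale linearly
except the all-pairs site comparison, which is quadratic in the number of
qualifying sites.

## Known limitations

* No aromatic stacking, cation–π or halogen-bond detection — polar
  contacts only, by scope.
* Hydrogen-free criteria cannot distinguish donor/acceptor roles in
  ambiguous side chains (His tautomers, Asn/Gln flips); roles are taken
  from residue tables at face value.
* mmCIF input is not implemented; PDB only.
* Fragment matching is 3D-graph-based and assumes reasonable geometry; a
  ligand with badly distorted bond lengths may fail bond inference.
* The theme-discovery problem itself is out of scope: themes are consumed
  as annotations, never computed.
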