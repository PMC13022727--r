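---
title: "Higher-level retrosynthesis: synthon abstraction, template relevance, and substructure-terminated search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Higher-level retrosynthesis: synthon abstraction, template relevance, and substructure-terminated search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrosynthon)
```

## The model

Computer-aided retrosynthesis tools usually plan at the level of fully
specified molecules: every proposal fixes the leaving group, the protecting
groups, and every tactical interconversion along the way. Chemists do not
think this way; they first choose a *strategy* — which bonds to form, in
which order, from which synthons — and defer the *tactics* (which halide,
which ester, which protecting group) until the route is settled.

This package implements that idea as a complete data-to-planner pipeline:

1. **Route mining.** Atom-mapped reaction records are grouped per source
   document, assembled into a network of single-step reactions (molecules
   deduplicated by canonical structure, duplicate reactant-product pairs
   collapsed, cycles broken in favour of the earlier record), and one
   multistep route is extracted per terminal product.
2. **Atom provenance.** Within each route, every atom of every intermediate
   is traced through the atom maps to decide whether its lineage reaches the
   final target (*core*) or not (*leaving*). Implicit hydrogens present on a
   core atom in an intermediate but absent on that atom in the target are
   counted as leaving attachments; this is what makes amine protections and
   N-acylations abstract consistently.
3. **Abstraction.** Each maximal connected leaving substructure is deleted
   and replaced by one marker per core-attachment bond. Markers on
   heteroatom cores form a single HET class; markers on carbon cores are
   classed by the Pauling electronegativity of the attached leaving atom
   relative to carbon: C(+) (electrophilic carbon; halides, triflates,
   other oxygen leaving groups), C(−) (nucleophilic carbon; boron, metals,
   hydrogen), or C-neutral inside the threshold band. The signs follow
   charge-affinity notation, not formal charges. Carboxylic acids, esters
   and acyl halides thereby collapse to one acyl cation equivalent, and any
   aryl halide or pseudohalide to one aryl electrophile.
4. **Tactical-step removal.** A step whose abstracted principal reactant is
   structurally identical to its abstracted product only manipulates
   leaving substructures (hydroxyl-to-triflate interconversions,
   acid-to-acyl-chloride activations, protections whose freed hydrogen is
   itself consumed later). Such steps are deleted and their endpoints
   merged, so higher-level routes are never deeper than their concrete
   sources.
5. **Templates and the single-step model.** Retro templates are extracted
   from each abstracted (or concrete) reaction as the changed-atom core
   plus a context radius, consolidated to the most general form that still
   recovers the recorded reactants, and ranked for a query product by a
   feedforward classifier over a marker-aware circular fingerprint.
6. **Planning.** A select–expand–update tree search proposes abstracted
   precursors recursively. A node terminates when it matches the buyables
   catalog — exactly, in the original formulation, or by marker-aware
   substructure matching in the higher-level formulation, where a marker
   position accepts any substituent whose attachment atom satisfies the
   marker's electronegativity class, or an implicit hydrogen whose class
   at that core atom equals the marker's — HET on heteroatoms (a free
   amine matches a protected-amine query), C(−) on carbon (a terminal
   alkyne matches an alkynyl-nucleophile query) — mirroring how the
   abstraction classes leaving hydrogens. Matched buyables are reported
   per terminal as a guide for instantiating the route.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `threshold` | 0.1 | Half-width (Pauling units) of the C-neutral band around carbon (EN 2.55). Hydrogen (2.20) falls below the band, so C–H nucleophile equivalents class as C(−). |
| `radius` (templates) | 1 | Context bonds around changed atoms; multiply-bonded O/N/S neighbours are always included whole. Consolidation pools radii {1, 0}. |
| `bits`, `fp_radius` | 2048, 2 | Folded circular count fingerprint; marker class and multiplicity enter the initial atom invariants, so C(+) and C(−) environments hash apart. |
| `hidden`, `epochs`, `lr`, `batch` | 512, 40, 0.05, 32 | One-hidden-layer ReLU network with softmax cross-entropy, mini-batch gradient descent with momentum 0.9, early stopping on validation top-1. |
| `expansion_width` | 25 | Top-scoring templates applied per node expansion. |
| `exploration_const` | 1.4 | PUCT-style constant: score = value + c · prior · sqrt(parent visits) / (1 + visits); the value of a chemical node is the fraction of its descendant molecules resolved to buyables. |
| `max_depth`, `max_iterations` | 10, 100 | Search depth and model-call budget. |

All of these are fields of `default_config()` and flow through the
`cmd_*` pipeline commands; every command writes its resolved configuration
next to its outputs and funnels all randomness through one seed, so reruns
are bit-identical (curation) or metric-identical (training).

## The synthetic corpus and what it does (not) show

There is no freely redistributable atom-mapped patent corpus that would fit
in a test suite, so the package ships a generator that *assembles* routes
forward from enumerated aryl/alkyl building blocks through nine
scaffold-building families (biaryl and alkynyl couplings, amide, ester and
sulfonamide formation, N-arylation, N- and O-alkylation) plus benzyl
deprotection, with tactical detours planted at known positions:
triflation before a coupling, acid activation before an acylation, and Boc
protection/deprotection pairs. Every atom carries a persistent identity
through the assembly, so the generator knows exactly which atoms are
leaving, which hydrogens are consumed, and which records are tactical —
*independently* of the map-following provenance tracer that is being
tested. Reagent donors (triflic anhydride, Boc anhydride, oxalyl chloride)
appear as mapped co-reactants so that every product atom has a reactant
origin.

The generator emulates: per-document multistep routes (including convergent
shapes), functional-group variants of one strategy, patent-style
per-record atom maps, and an adversarial "variant" stock in which every
starting material is replaced by a different leaving-group variant of the
same abstracted form (bromide to iodide, boronic acid to stannane, amine to
Boc carbamate, ...). It does **not** emulate: mapping errors and noise,
reagent/condition diversity, stereochemistry, ring-forming
transformations, or the scale and redundancy of real corpora. Green tests
therefore certify the correctness of the machinery (provenance equals
planted truth, templates round-trip, search is oracle-complete), not
real-data performance numbers.

Study problem sizes were chosen to keep each experiment meaningful and the
whole suite practical: the abstraction/curation study uses 100 multistep
routes; the planner studies use 10–12 targets against exhaustive
breadth-first oracles; the model-recovery study uses 2000 unique pairs.

## The single-step study corpus

The template-relevance experiment uses the generator's *single-step*
configuration (one scaffold-building step per document, 10 template
families). The multistep configuration is unsuitable for measuring
classifier quality: a multistep target contains several formed linkages,
each a chemically valid disconnection, so the recorded family is only one
of several correct answers and the achievable top-1 is bounded by that
ambiguity (measured around 0.45 here), a property of the labels rather than
of the model.

One genuine ceiling remains even in the single-step corpus. The biaryl
retron `c–c` is orientation-symmetric: applying the coupling template to
any biaryl product yields two polarity assignments (either ring may carry
the C(+)), both chemically meaningful, and the recorded precursor is —
under the pessimistic convention that ranks the ground truth last within
its own template's proposals — at rank 2 at best. With biaryl couplings at
roughly a quarter of the corpus, pessimistic top-1 saturates near 0.75
(observed ≈ 0.70) even though validation template accuracy is ≈ 0.98 and
pessimistic top-3/top-5 reach ≈ 99.5/100%. This is a faithful property of
the pessimistic metric on symmetric retrons, not a training failure, and it
is why the package reports the full top-k profile rather than a single
rank-1 number.

## Numerical and design choices

* **Canonical serialization** uses a colored canonical graph labeling
  (bliss, via igraph) on an auxiliary graph whose subdivision vertices
  carry bond orders; atoms are emitted in canonical rank order, fragments
  sorted bytewise. Atom maps never influence ranks. Aromaticity is taken
  from the input (lower-case/aromatic-bond notation) without perception,
  and a single bond between two aromatic atoms is always written `-`, so
  serialization round-trips are exact.
* **Cross-step atom alignment.** Patent-style records number atoms per
  record, so the product instance of one step is aligned to the matching
  reactant instance of the next by canonical ranks. The alignment is
  defined up to graph automorphism; generated corpora keep atom fates
  constant on automorphism orbits, and the ground-truth tests would expose
  any violation.
* **Stereo tags** are carried through parsing and serialization, but a tag
  whose parity reference (a leaving neighbour) is abstracted away is
  dropped with a warning; marker-bearing stereocentres are otherwise left
  untouched and no claim of stereochemical round-tripping is made.
* **Template consolidation** partitions reactions by their minimal-radius
  (changed-core) template identity. Within a family the identity embedding
  guarantees that the family's radius-0 template recovers every member, so
  it is the most general recovering template under the package's
  generality order (recovery-set inclusion, ties to fewer pattern atoms,
  then lexicographic id); cross-family recovery would require two distinct
  rewrites to reproduce identical recorded reactants. The acceptance suite
  nevertheless re-verifies every assignment by actually applying the
  assigned template.
* **Degenerate inputs.** Multi-product records keep the largest product by
  heavy-atom count (or are rejected, per configuration); records whose
  product atoms lack reactant origins are flagged, not repaired; spectator
  reactants abstract to nothing and are dropped with a signal; a route
  collapsing to zero higher-level steps is emitted empty with a flag.
* **Tie-breaks** are deterministic everywhere: template score ties resolve
  by template index, precursor sets sort by canonical string, buyable
  matches sort by heavy-atom count then string (capped at 10 per
  terminal), and all string ordering uses byte (radix) collation so
  outputs are locale-independent.

## Known limitations

* The SMILES dialect covers the organic subset, bracket atoms, charges,
  isotopic marker pseudo-atoms and aromatic notation, but not reaction
  component grouping, quadruple bonds, or kekulization of alternative
  aromatic spellings: two inputs of one molecule must use the same
  aromatic convention to canonicalize identically (the pipeline always
  compares its own serializations, which satisfy this).
* Polarity classing by a single electronegativity threshold is a
  deliberately coarse stand-in for a full treatment of nonpolar couplings
  and cycloadditions; the C-neutral class absorbs those cases and is
  documented as an approximation.
* The planner's value function (fraction of descendants resolved to
  buyables) is one reasonable choice among several; the oracle-equivalence
  test guarantees that search *completeness* does not depend on it, only
  efficiency does.
* Higher-level routes still need a chemist (or future tooling) to
  instantiate markers with concrete functional groups; the per-terminal
  buyable match lists are the hand-off point.
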