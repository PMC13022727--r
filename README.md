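# retrosynthon

Higher-level (synthon-abstracted) retrosynthesis planning in R.

Conventional computer-aided synthesis planning proposes fully specified
precursors, so it spends its search budget distinguishing chemically
equivalent choices — bromide vs. triflate, acid vs. ester vs. acyl chloride
— and wading through tactical steps (functional-group interconversions of
leaving groups, protections) that build nothing. `retrosynthon` implements
the *higher-level* alternative: atoms along mined multistep routes whose
lineage never reaches the final target are identified as **leaving atoms**
and replaced by polarity-classed attachment markers on their core atoms,

* `[1*]` — HET: marker on a heteroatom core,
* `[2*]` — C(+): electrophilic carbon (leaving atom more electronegative
  than carbon, e.g. halide or triflate carriers),
* `[3*]` — C(−): nucleophilic carbon (boron, metals, hydrogen),
* `[4*]` — C-neutral: within the electronegativity band around carbon,

so that any chloro/bromo/iodo/triflyl coupling becomes one C(+)+C(−)
disconnection and every acid derivative one acyl cation equivalent. Steps
whose abstracted reactant equals their abstracted product are tactical and
are removed, shortening routes. From the curated higher-level reaction
pairs the package extracts and consolidates retro templates, trains a
template-relevance classifier (circular marker-aware fingerprint in, one
hidden layer, softmax over templates, pessimistic top-k evaluation), and
plans multistep syntheses by a select–expand–update tree search whose
terminal test matches buyable building blocks *by substructure*: a marker
position accepts any substituent whose attachment atom satisfies the
marker's class, or a plain hydrogen where hydrogen itself carries that
class (HET at heteroatoms, C(−) at carbon).

Everything chemical is built in: a mapped-SMILES dialect with canonical
serialization (bliss canonical labeling with bond-order colors), a
graph-rewrite template engine (LAD subgraph monomorphism), per-document
route mining with atom provenance, and a seeded synthetic patent-like
corpus generator whose planted ground truth (leaving atoms, tactical
steps, family labels) validates every stage end to end.

## Worked example

```r
library(retrosynthon)
cfg <- utils::modifyList(default_config(), list(
  n_documents = 40L, p_tactical = 0.5, p_obn = 0.2, min_steps = 2L,
  max_steps = 3L, fp_bits = 512L, hidden = 32L, epochs = 15L, seed = 7L))

corpus <- cmd_simulate("demo", cfg)                       # records + stocks
cur <- cmd_curate("demo/records.tsv", "demo/curated", cfg) # mine + abstract
tr  <- cmd_train(cur$hl, "demo/model", cfg)                # templates + model
pl  <- cmd_plan("demo/targets.txt",
                list(model = tr$model, templates = tr$cons$templates),
                "demo/buyables_variant.txt", "demo/plans",
                mode = "higher", config = cfg)
```

The 40 mined routes average depth 3.2 before abstraction and 2.7 after —
the planted triflations, acid activations and Boc protections are removed
(`demo/curated/route_stats.csv` lists the per-route pairs). Curation keeps
111 unique higher-level reactant–product pairs versus 131 concrete ones:
leaving-group variants of one strategy collapse. Training prints the
held-out table (12 test pairs at this toy scale):

```
Top-k accuracy (pessimistic, n = 12):
  top-1     16.7%
  top-3     41.7%
  top-5     91.7%
  top-10   100.0%
```

Planning against the *adversarial* stock — every starting material
replaced by a different functional-group variant of the same abstracted
form, so exact lookup finds nothing — still succeeds for 100% of targets:

```
first target: C(c1c(c(ccc1)CNc2c(c(ccc2)Cl)OC)OC)(NCCC)=O
solved in 2 iterations; 2 reactions, depth 2
leaf buyable matches:
  [1*]Nc1c(c(ccc1)Cl)OC  ->  C(Nc1c(c(ccc1)Cl)OC)(=O)OC(C)(C)C
  [2*]C(c1c(c(ccc1)C[2*])OC)=O  ->  C(c1c(c(ccc1)CI)OC)(=O)O
  [1*]NCCC  ->  C(NCCC)(=O)OC(C)(C)C
```

Each abstracted leaf is reported with the concrete buyables that
structurally match it — here a Boc-protected aniline standing in for the
free amine (HET marker), and a benzylic iodide matching the C(+) position —
which is exactly the hand-off a chemist uses to instantiate the route.

The on-disk dialect for abstracted molecules is standard SMILES with
isotope-labelled attachment pseudo-atoms: class 1–4 as above, and a
multiplicity m > 1 encoded as isotope `10·m + class` (`[21*]` = doubled
HET marker).

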