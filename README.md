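# evoligand

Genetic-algorithm design of small-molecule protein binders, with the
molecule itself as the chromosome.

## The problem

Screening-based drug discovery is bounded by its database: public compound
collections hold $10^6$–$10^{13}$ structures, while the space of neutral
organic molecules over {C, N, O, P, S, F} reaches roughly $10^{80}$ at a
hundred heavy atoms. evoligand searches that space directly. Each individual
in the population is a **non-isomeric Kekulé SMILES string**; genetic
operators edit the parsed molecular graph and re-serialize it, so every
candidate in every generation is a chemically valid, connected molecule.

The fitness of a chromosome $x$ is minimized:

$$F(x) = -\max_{s \in \mathrm{stereo}(x)} S(s) + P_{\mathrm{ADME}}(x) +
P_{\mathrm{sub}}(x) + P_{\mathrm{hb}}(x) + P_{\mathrm{loc}}(x)$$

where $S$ is a binding-site score over the molecule's enumerated
stereoisomers (capped at 512 by default) and the penalty terms encode
Lipinski Rule-of-5 / rotatable-dihedral ADME heuristics (soft or hard),
forbidden substructures such as enol ethers, required hydrogen bonds to
named residues, and spatial localization in the site. Unparseable or
unscorable chromosomes get the sentinel fitness 0. The scorer is pluggable:
a deterministic surrogate site model and a replay scorer ship with the
package; external docking engines attach through the same contract.

The engine is a classic generational GA — stochastic-uniform selection over
rank weights, 10% elitism, independent crossover/mutation probabilities of
0.8/0.8, fourteen named molecular mutations (atom change/insert/delete,
branch grow/excise, ring close/open, dihedral branch interchange, six
bond-order transitions) plus a SMILES segment-exchange crossover — with
per-generation checkpointing and exact restart.

## Worked example

Measure aspirin, then evolve a population of 30 aspirin copies toward a
surrogate site that favours a larger, monocyclic, moderately flexible
binder, under soft ADME restrictions:

```r
library(evoligand)

asp <- parse_smiles("CC(=O)OC1=CC=CC=C1C(=O)O")
compute_properties(asp)
#> <property_profile> heavy=13 mass=180.16 hbd=1 hba=4 rot=3 rings=1 tetra=0 stereo_db=0 log_kow=-

site <- synthetic_site_scorer(
  target = c(heavy_atoms = 19, hbd = 1, hba = 2, n_rings = 1,
             rotatable_dihedrals = 5),
  s_max = 100)

history <- run_ga(rep("CC(=O)OC1=CC=CC=C1C(=O)O", 30), site,
                  ga_config(generations = 20, seed = 42),
                  adme = adme_config("SoftLipinski"))
history
#> <run_history> 20 generations, population 30, scorer synthetic_site
#>   best fitness: -100.0000  (generation 15)

report <- generate_report(history)
head(report[, c("smiles", "best_fitness", "heavy_atoms",
                "rotatable_dihedrals", "n_rings")], 3)
#>                           smiles best_fitness heavy_atoms rotatable_dihedrals n_rings
#> 1 C1CC=C=CCCC1=CC=C=CC=CCCC(=O)O         -100          19                   5       1
#> 2 C1CC=C=CCCC1=CC=C=CCCC#CC(=O)O         -100          19                   5       1
#> 3 C1CC=C=CCCC1=CC=C=CC#CCCC(=O)O         -100          19                   5       1
```

By generation 15 the population has found molecules whose profile matches
the target exactly (score 100, fitness −100, zero ADME penalty): 19 heavy
atoms, one ring, five rotatable dihedral bonds. The report is the sorted,
unique union of every generation, deduplicated by a canonical
graph-isomorphism key — the cumulated allene/alkyne motifs are a reminder
that the surrogate scores a *profile*, not chemistry a medicinal chemist
would sign off; with a real docking adapter the same machinery optimizes
real poses, and the substructure penalties prune motifs you declare
unwanted.

The structural layer works standalone. The macrocyclic protease inhibitor
simeprevir, as its non-isomeric SMILES, gives:

```r
sim <- parse_smiles(fixture_smiles("simeprevir"))
compute_properties(sim)
#> <property_profile> heavy=52 mass=749.95 hbd=2 hba=12 rot=8 rings=7 tetra=5 stereo_db=0 log_kow=-
length(enumerate_stereoisomers(sim))
#> [1] 32
```

— 52 heavy atoms, 750 Da, 2 H-bond donors, 7 SSSR rings, and $2^5 = 32$
stereoisomers from its five tetrahedral centers (the in-macrocycle double
bond is geometry-fixed and not enumerated).

A thin command-line front end wraps the same functions
(`inst/cli/evoligand.R`: `run`, `evaluate`, `props`, `stereo`, `report`,
`fixtures`).

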