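---
title: "Evolving small-molecule ligands on SMILES chromosomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolving small-molecule ligands on SMILES chromosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evoligand)
```

## The model

evoligand treats de novo ligand design as a search over the space of neutral
organic molecules built from the alphabet C, N, O, P, S, F. That space is
astronomically larger than any screening database — on the order of $10^{80}$
structures at a hundred heavy atoms — so the package searches it with a
genetic algorithm whose individuals are *non-isomeric Kekulé SMILES strings*.
The string is the chromosome: crossover and the fourteen molecular mutations
act on its parsed molecular graph and re-serialize the result, so ring
numbering is regenerated on every edit and chemical validity (valence
arithmetic plus connectivity) is re-checked after every operation.

Fitness is a minimized scalar

$$F(x) \;=\; -\max_{s \,\in\, \mathrm{stereo}(x)} S(s) \;+\;
  \underbrace{P_{\mathrm{ADME}}(x) + P_{\mathrm{sub}}(x) +
  P_{\mathrm{hb}}(x) + P_{\mathrm{loc}}(x)}_{\text{penalties} \;\ge\; 0},$$

where $S$ is a binding-site score ($\ge 0$, larger = stronger predicted
binding) evaluated on every enumerated stereoisomer of the chromosome up to a
cap, and the penalties encode oral-drug (Lipinski) heuristics, forbidden
substructures, required hydrogen bonds, and spatial localization. A
chromosome that cannot be parsed or scored at all receives the sentinel
fitness 0. The sentinel is kept exactly as specified even though it can rank
*better* than a valid positive fitness (score smaller than penalties); this
sharp edge is deliberate and documented rather than clamped.

The scorer is a contract, not an implementation: any function that maps
(graph, stereo assignment, profile) to a best-pose score plus an interaction
report can drive the evolution. The package ships two: a deterministic
surrogate site model and a file-backed replay scorer. Production docking
engines are adapters the user supplies; nothing in the core knows about 3D
coordinates.

### The surrogate site model

The built-in scorer represents a binding site as a target profile
$t = (\text{heavy atoms}, \text{HBD}, \text{HBA}, \text{rings},
\text{rotatable dihedrals})$ with weights $w$ and a ceiling $s_{\max}$:

$$S(x) = \max\!\big(0,\; s_{\max} - \textstyle\sum_i w_i\,|p_i(x) - t_i|\big).$$

This is a test double for a docking engine, chosen so that every contract
property of the real pipeline — determinism, best-of-stereoisomers
aggregation, penalty additivity, interaction-report plumbing — can be
exercised exactly and cheaply. What it does *not* emulate: pose geometry,
score stochasticity, the ruggedness of a physical scoring landscape, or any
stereochemical discrimination (all stereoisomers of a molecule score
identically, so the engine reuses the first assignment's score when the
scorer declares itself stereo-insensitive). Passing the surrogate-based
suites therefore demonstrates the correctness of the evolutionary machinery,
not predictive power against a real protein.

## The molecular-graph layer

**Dialect.** Chromosomes are written in a deliberately narrow Kekulé dialect:
uppercase atoms, bonds `-`, `=`, `#`, branches, ring-closure digits and
`%nn`. Aromatic rings are always spelled with explicit alternating bonds; no
aromaticity model exists anywhere in the package, which keeps every validity
check pure valence arithmetic. Stereo marks (`@`, `/`, `\`) are accepted on
input and dropped — stereochemistry lives in the enumeration layer, never in
the chromosome.

**Valence model.** C4, N3, O2, P3, S2, F1, implicit hydrogens filling the
remainder. Sulfur is promotable to 4 or 6 *on input only*, because marketed
sulfonamide drugs (an S(=O)(=O) group) must parse; mutation operators only
ever create divalent S. A lenient parsing mode (`strict = FALSE`) floors
implicit hydrogens at zero and flags the offending atoms instead of
erroring; it exists because printed literature structures are not always
valence-perfect (one registry fixture carries a pentavalent ring carbon as
published), and measuring such a structure is still meaningful. Chromosomes
admitted to a population always pass the strict check.

**Rings.** The ring count is the cyclomatic number $|E|-|V|+1$; the SSSR is
computed as a minimum cycle basis (Horton candidate cycles from shortest
paths, greedy GF(2) independence). The ring-bond census distinguishes "bonds
that could open" (any bond on a cycle, i.e. any non-bridge edge) from bonds
whose removal actually destroys the largest ring: a bond shared between the
macrocycle and a fused small ring merges the two into an even larger ring
when removed, and so does not count as an opener. On the macrocyclic
protease-inhibitor fixture this yields 39 ring bonds of which 12 open the
14-membered macrocycle — one off the hand count quoted alongside the
structure, a known sensitivity of this census to the fused-ring convention.

**Stereo perception.** Tetrahedral centers are sp3 atoms with four
substituents (at most one implicit H) that are pairwise structurally
distinguishable; stereogenic double bonds are *acyclic* order-2 bonds with
two distinguishable substituents at each end. Distinguishability is decided
by iterative neighbourhood refinement of the graph with the center removed —
two substituents are interchangeable iff their refined classes coincide.
Ring double bonds are excluded because their geometry is fixed by the ring;
this is the only convention under which the macrocyclic fixture has exactly
$2^5 = 32$ stereoisomers (five tetrahedral centers, in-ring C=C not counted)
while the chain-unsaturated fixtures have $2^3 = 8$. C=N double bonds are
not treated as stereogenic (the lone pair is not counted as a substituent);
oximes are thereby under-counted, a known limitation. Enumeration is
lexicographic over the $(\pm)$/(cis, trans) basis with the last element
varying fastest, capped at `max_stereoisomers` (default 512), so
"stereoisomer $k$ of $2^n$" is reproducible across runs.

**Rotatable dihedrals.** The literature the fixtures come from never defines
its convention, so the package uses the one rule that reproduces all four
printed counts simultaneously (aspirin 3, the 19-atom edited design 7, the
vinyl aspirin variant 6, the macrocyclic drug 8, and also the ring-opened
derivative's 19): a non-ring single bond whose endpoints both have at least
two heavy neighbours, excluding amide C(=O)–N bonds. Two further printed
counts disagree with this rule by one; the registry stores the computed
values for those.

**Canonical keys.** Deduplication in reports uses a BLISS canonical
permutation of the bond-subdivided, vertex-coloured graph, giving a key that
is equal iff two molecules are isomorphic as element/bond-order labelled
graphs. The key deliberately ignores stereo and is *never* the chromosome:
multiple SMILES spellings of one molecule are distinct chromosomes and
legitimate parallel search paths.

## Operators

All fourteen mutations draw their site uniformly over feasible sites, and
atom insertions/substitutions draw elements from `unnorm_percent_atom`
restricted to valence-feasible symbols (which biases towards carbon, the
most substitutable element). Dispatch weights are *named*, not positional:
the probability vector keys off operator names so that enabling or
disabling operators can never silently shift meaning. Open design points
were resolved as follows:

* `CLOSE_RING` is feasible between atoms with free valence at graph distance
  2–7, creating rings of size 3–8. The tabulated bond-length machinery
  (`inter_bond_distance` × `cutoff_bond_percentage`) is honoured as an
  optional geometric post-filter when a 3D-capable scorer supplies
  coordinates; the core stays 3D-free.
* `OPEN_RING` removes one of the chromosome's own ring-closure digit bonds —
  not an arbitrary in-ring bond (that scission, `OPEN_BOND`, is deliberately
  absent from this operator set). Under uniform choice over the macrocyclic
  fixture's seven closures, the macrocycle opens with frequency 1/7, which
  the suite verifies by Monte Carlo.
* `INTERCHANGE_DIHEDRAL` is read as a branch exchange across an acyclic
  single bond: one detachable substituent from each side swaps attachment
  points. A non-isomeric chromosome cannot express a cis/trans flip, so this
  is the only reading that both changes the molecule and conserves its
  formula; formula conservation is asserted property-style.
* `ADD_BRANCH` seeds a single atom; longer branches grow over generations.
  `DELETE_BRANCH` excises a whole terminal subtree, and requires a genuine
  branch point (anchor of heavy degree ≥ 3), so an unbranched chain has no
  deletable branch.
* Crossover picks a random non-ring atom in each parent (ring atoms are
  blocked — a ring cannot be split by one cut — and re-picked up to
  `max_tries` times), then swaps the two SMILES-subtree right-segments. A
  child that fails validation or falls below `min_heavy_atoms` is replaced
  by its parent's copy; crossover and mutation never raise and never return
  an invalid molecule.

## The generational engine

Selection is stochastic-uniform by default (roulette and 2-tournament are
provided). Raw fitnesses are negative and unbounded, so selection operates
on rank-based weights $w \propto 1/\sqrt{\mathrm{rank}}$ with average ranks
on ties — sign-safe, scale-free, and symmetric for equal-fitness
populations. Crossover (0.8) and mutation (0.8) are *independent* per-slot
probabilities: rates summing past 1 cannot be complementary, and the many
molecular mutations are undersampled at conventional low mutation rates.
The elite (10% by default) is carried unchanged and — under a deterministic
scorer — not re-scored, which makes the best-fitness trace provably
non-increasing. A `rescore_elites` flag forces re-evaluation for stochastic
scorers, reproducing the non-monotone best-fitness traces docking engines
produce. `tol_con` is accepted in configuration but inert: constraints enter
the fitness as penalties, no nonlinear-constraint solver exists to consume
it.

Termination: a fixed generation budget, or stall — the best fitness
improving by less than `tol_fun` (0.02) over `stall_gen_limit` (100)
generations. Every generation is checkpointed together with the RNG state;
restarting from a checkpoint replays the interrupted run bit-for-bit, which
the suite verifies by killing a run at generation 7 and comparing the
resumed history against an uninterrupted one.

## Penalties and their scaling

Soft Lipinski penalties charge `coefficient × max(0, (x − limit)/limit)` per
rule — *relative* violation, not the raw excess. With the default mass
coefficient 4, a raw `(mass − 500) × 4` would reach hundreds for modest
violations and drown any score on the 10–100 scale a docking engine
produces; the relative form keeps penalties commensurate while remaining
monotone in each violated quantity. The raw form stays available behind
`soft_scale = "raw"`. Hard mode charges 20 per violated rule. The
octanol-water partition coefficient is input-only: if the user supplies
`log_kow` it joins the rule set (limit 5), otherwise the rule is skipped —
the package never estimates it. Acceptors default to the N+O count; a
pharmacophore-style override is accepted because published acceptor counts
(e.g. 10 for the macrocyclic fixture, against 12 N+O) use tighter
definitions.

Penalties combine *additively* with the negated score. Forbidden
substructures are matched by VF2 subgraph isomorphism on the same
vertex-coloured representation as the canonical key, counting distinct
matched atom sets; patterns flagged `terminal` must land their final atom on
a branch end-point, which is how "–SH at the end of a branch" is expressed
without a full query language.

## Problem sizes and numerical choices in the suite

The test harness exercises the engine at sizes chosen to make each property
sharply falsifiable: ten thousand seeded operator applications (mutations
chained from the aspirin and macrocycle fixtures plus segment crossovers
between them) with a serialize–reparse validity oracle; the convergence
harness starts three seeded runs from 40 random C4–C6 alkanes against a
surrogate targeting a 19-heavy-atom monocycle ($s_{\max} = 100$) and
requires the best fitness to come within 10% of $-s_{\max}$ inside 50
generations (runs stop earlier via the stall rule once converged); the
restricted-vs-unrestricted contrast pairs two 18-generation runs on one
seed against a site that rewards flexibility beyond the dihedral limit, so
the soft-ADME penalty demonstrably binds. SSSR perception is cross-checked
against a brute-force minimum-cycle-basis oracle on exhaustively enumerated
simple cycles of randomly grown small molecules under a fixed seed.

## Known limitations

* No aromaticity, tautomers, charges, isotopes, or pH states; neutral
  organics over C, N, O, P, S, F only.
* Stereo perception by neighbourhood refinement can in principle merge
  non-equivalent substituents on pathological near-regular graphs; on
  drug-like molecules (and on every registry fixture) it is exact.
* The surrogate site cannot distinguish stereoisomers, so best-of-stereo
  aggregation is only meaningfully exercised by the replay scorer.
* log K_ow is user-supplied or absent; database-backed estimation is out of
  scope by design.
* The engine optimizes a single scalar objective; multi-site or
  multi-objective toxicity screening multiplies scorer calls and is not
  included.
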