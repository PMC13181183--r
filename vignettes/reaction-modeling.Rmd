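---
title: "Joint atom mapping, reaction centers and classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint atom mapping, reaction centers and classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxngraph)
```

`rxngraph` treats a chemical reaction as a pair of molecular graphs — the
reactant set $G_R$ and the major product $G_P$ — and learns three coupled
predictions jointly: a soft atom-to-atom correspondence between product and
reactant atoms, binary reactivity labels on product atoms and bonds (the
reaction center), and a global reaction class. This vignette explains the
model, the assumptions behind it, the tunable parameters, what the
synthetic generator does and does not emulate, and the numerical and design
choices a maintainer should know about.

## Graph representation and featurization

Molecules are heavy-atom graphs: hydrogens are implicit and enter only as
per-atom counts (a feature and a labeling signal). A graph may have several
connected components, which is how multi-molecule reactant sides and
reagents are represented without special handling. Atom features are
one-hot blocks over closed vocabularies — element
(C, N, O, S, P, F, Cl, Br, I, B, Si, Sn, Se, Cu, Zn, Mg), formal charge
($-2\ldots+2$), chirality tag, hybridization, degree (0–6), hydrogen count
(0–4) — plus aromaticity and ring-membership flags; bond features cover
type, conjugation, stereo and ring membership. Every categorical block ends
in a reserved *other* bucket, so featurization is total and the widths
($d_x = 47$, $d_e = 11$) are constants of a run. The vocabularies are a
documented stand-in choice: they cover the species of organic reaction
corpora, and anything rarer degrades gracefully into *other* rather than
failing.

The SMILES layer is deliberately scoped: organic-subset and bracket atoms,
aromatic lowercase notation, ring closures (including `%nn`), branches,
dots, charges, atom maps and tetrahedral tags, with implicit-hydrogen
assignment by standard valence rules and perception of six-membered
alternating C/N rings as aromatic. Stereochemistry beyond the feature bits,
3D information, and protonation-state normalization are out of scope.
Canonicalization uses Morgan-style iterative rank refinement with
individualization of tied classes; for molecules whose refinement classes
coincide with automorphism orbits — which holds for all fixture-scale
molecules here, and is itself tested against brute-force orbit enumeration —
the canonical SMILES is invariant to input atom order. All internal indices
are 1-based (R convention); SMILES atom-map numbers remain arbitrary
positive integers and are renumbered $1\ldots|V_P|$ in canonical product
order by `canonicalize_and_remap()`.

## Encoder

Both graphs are encoded by one shared stack of edge-aware message-passing
layers: each layer aggregates $\mathrm{relu}(h_j + W_e e_{ij})$ over
neighbours, combines with $(1+\epsilon)\,h_i$, applies a two-layer MLP, and
mixes update and input through a learnable scalar gate
$g\,\mathrm{update} + (1-g)\,\mathrm{input}$ — the "dynamically weighted
skip connection" realized in its simplest learnable form. Sharing the
encoder between reactant and product passes is essential: the matching
head compares the two embedding spaces directly.

Defaults follow the reference configuration (5 layers, 512 dimensions, 8
attention heads); the desk-scale runs in this package use 4 layers × 64
dimensions. Depth matters for mapping: a $k$-layer encoder cannot separate
two atoms whose distinguishing context lies more than $k$ bonds away, so
depth must cover roughly the radius of the largest scaffold. Four layers
suffice for the generator's default scaffolds; with longer chains, increase
`num_layers` before anything else.

## Soft matching and symmetry

The raw similarity $\hat M = H_P H_R^\top$ is pushed through Sinkhorn
scaling into a correspondence matrix. Two numerical choices deserve
emphasis:

- **Log domain.** The scaling runs on log-probabilities
  ($L \leftarrow L - \mathrm{logsumexp}$ sweeps), which is exactly
  equivalent to alternating row/column normalization of
  $\exp(\hat M/\tau)$ but stable for any input magnitude and temperature.
  The mapping loss — the mean negative log-likelihood of the true reactant
  atom per product row — is evaluated directly on $\log M$, so its
  gradient stays informative even when the truth entry's probability
  underflows. (An earlier probability-domain formulation with an
  $\varepsilon$-clamp silently zeroed those gradients and permanently
  stalled mapping training; the log-domain form removes the failure mode
  rather than papering over it.)
- **Capacity-constrained columns.** With $|V_P| < |V_R|$, full column
  normalization is infeasible jointly with row normalization, and it
  forces reactant atoms that *should* receive no mass — leaving groups,
  unmapped reagents — to extort probability from product rows, producing
  exact 50/50 ties on edited atoms. Wide matrices therefore only shrink
  columns whose mass exceeds one; square matrices use plain normalization,
  whose fixed point is doubly stochastic. Rows always end with a proper
  normalization, so every product atom carries a distribution over
  reactant candidates.

Sinkhorn defaults are 10 iterations at temperature 0.1 (both configurable;
the acceptance checks on raw random matrices use temperature 1, the
neutral choice for unscaled inputs). Hard assignments are row-wise argmax
with lowest-index tie-breaks — all tie-breaks in the package are
lowest-index and deterministic.

Molecular symmetry is handled by Weisfeiler–Lehman refinement: colors start
from (element, charge, aromaticity) and are rehashed with sorted neighbour
multisets to a fixed point (at most $|V|$ rounds). Final classes are
unions of automorphism orbits. They serve twice: `symmetry_refine()`
redistributes colliding hard assignments across unused members of the
targeted reactant class (greedy, lowest-index; infeasible collisions are
left in place and flagged), and symmetry-aware accuracy counts a
prediction correct when it lands in the truth atom's class — a benzene
ring rotation scores 1.0 while exact matching scores 0.

## Cross-attention, heads and losses

Each product atom attends to its single assigned counterpart. With one
candidate the attention softmax is identically 1, so each head's output
equals its value projection of the counterpart embedding; the query/key
projections are kept for structural fidelity but receive no gradient. The
assignment is the ground-truth map during training (teacher forcing) and
the symmetry-refined prediction at inference, with all parameters shared
between the two paths. Whether inference should instead consume the soft
row was an open design point; the hard refined assignment is the default
because it keeps training and inference inputs on the same support, and
the soft matrix remains available to callers.

The atom head is a per-atom MLP on $[H_P \| \tilde H_P]$; the bond head
concatenates both enriched endpoints, bond features, a dual-graph (line
graph) bond embedding, and both endpoint atom scores. Bond inputs for
$(i,j)$ and $(j,i)$ are averaged before the MLP, making scores
orientation-invariant by construction (the concatenation order is
otherwise arbitrary). The dual encoder is a separate, smaller GIN-style
stack (2 layers by default) without edge features. The classifier
mean-pools enriched product embeddings over a softmax with $K = 10$
classes by default.

In products-only mode the reactivity heads consume $[H_P \| 0]$ —
zero-padding rather than a narrower head, so one parameterization serves
both modes — while classification still uses the enriched path whenever
reactants are supplied; without reactants no mapping output exists.

Reactivity losses combine Dice overlap and focal cross-entropy,
$\lambda_{dice}\,L_{Dice} + (1-\lambda_{dice})\,L_{Focal}$ with
$\lambda_{dice} = 0.4$, focal $\gamma = 2$ and a positive-class weight of 5
(the upweighting factor is unspecified upstream; 5 is this package's
documented choice, configurable). The mapping loss form is likewise not
pinned down upstream; the row-wise NLL is the direct choice given
supervised maps, with the structural-consistency score exposed as an
optional diagnostic rather than a training term. Task combination is
either a fixed weighted sum or homoscedastic-uncertainty weighting
$\sum_i L_i/(2\sigma_i^2) + \log\sigma_i$ with learned log-variances held
fixed at inference; the two modes are mutually exclusive. Numerical clamps
use $\varepsilon = 10^{-8}$; Dice smoothing defaults to 1, which also
pins the degenerate all-negative/all-zero case at loss 0.

Training is AdamW (defaults: learning rate $10^{-4}$, weight decay
$5\times10^{-5}$, batch 32, early-stopping patience 10 on an equal-weight
scalarization of validation atom F1, bond F1 and class macro-F1 — the
scalarization weights are unstated upstream and equal weights are the
neutral choice). All gradients are hand-derived and verified against
finite differences in the test suite.

## The synthetic generator

`generate_reactions()` emulates an atom-mapped reaction corpus at desk
scale: ten transformation templates (ester, amide and ether couplings,
amine alkylation, alcohol oxidation, ketone reduction, elimination, ester
hydrolysis, deprotonation, aromatic bromination) applied to sampled alkyl
and aryl scaffolds, mirroring a 10-class benchmark structure. Templates
are written directly as graph edits, so the atom map, the reactive atom
set and the reactive bond set are exact by construction — the labeling
module is tested against them, not the other way round. A configurable
fraction of reactions (default 0.3) uses aromatic scaffolds with
WL-nontrivial symmetry to stress mapping ambiguity; atom orders are
randomly permuted by default to defeat positional shortcuts; leaving
groups and reagents (bromide, sodium, water, the ester alcohol) appear as
unmapped reactant atoms so rectangular matching is exercised.

One identifiability rule: the symmetric-linker templates (R–O–R′, R–NH–R′)
draw distinct fragments for the two sides. If the fragments were equal the
product would carry an automorphism that the two-molecule reactant side
does not share, and the ground-truth map would be ambiguous *in principle*
— no method, and no symmetry-aware metric, could resolve it. Keeping the
truth identifiable up to graph symmetry is a property of a well-posed
testbed, matching how curated benchmarks define mapping ground truth.

What the generator does **not** emulate: reagent-rich patent reactions
with dozens of spectator atoms, stereochemical edits, multi-step or
ring-forming transformations, noisy or partially wrong maps, and the heavy
class imbalance of real corpora (class weights are configurable but
default to uniform). Passing tests on this substrate demonstrates that the
mechanisms — matching, refinement, labeling, the heads, the losses — are
implemented correctly and can be driven to perfect desk-scale accuracy; it
does not certify benchmark-scale accuracy on real patent data, which
requires orders of magnitude more data and capacity.

## Problem sizes and determinism

Desk-scale runs used throughout the package's own evaluation: 50 generated
reactions, a 4-layer × 64-dimension encoder with 4 heads and a 2-layer
dual encoder, batch 10, AdamW at $2\times10^{-3}$ — chosen so a full
training run finishes in well under a minute on one CPU while the
reference defaults (5 × 512 × 8 at $10^{-4}$) remain the configuration
shipped for larger studies. Under these conditions full-mode training
reaches 100% train-set top-1 edit accuracy, classification accuracy and
symmetry-aware mapping accuracy within about 40 epochs; the labeling
module reproduces generator ground truth exactly on 1,000 reactions.

Every stochastic component — parameter initialization, batch shuffling,
the generator — draws from an explicit seed, and the RNG state is saved
and restored around library calls, so generate → train → evaluate is
bit-reproducible on CPU.

## Known limitations

- The SMILES dialect is scoped as described; exotic valences, isotopes
  (parsed, ignored) and extended stereochemistry are not modeled.
- Canonical invariance is guaranteed only when refinement classes equal
  automorphism orbits; WL-hard regular graphs could in principle defeat
  it, though they do not occur among valence-bound molecules at this
  scale.
- Aromaticity perception covers six-membered alternating C/N rings;
  five-membered aromatics must be written in aromatic notation.
- `symmetry_refine()` resolves collisions within a product WL class;
  collisions across classes are left to the matching quality itself.
- The training loop is plain R; it is comfortable at hundreds of
  reactions and tens of thousands of parameters, not at benchmark scale.
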