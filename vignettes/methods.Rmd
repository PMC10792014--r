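---
title: "Models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famrecon)
```

famrecon packages the computational core of a gene-family
macroevolution study of the kind applied to the chemokine signalling
system: how many copies of each family did ancestral genomes carry,
where in the species tree did families originate and expand, which
sequences are homologous at all, and how trustworthy are the branches
those conclusions rest on. Every stage is exercisable on synthetic
families with complete ground truth, so the package's claims about its
own correctness are mechanically checkable. This vignette records the
models, the numerical conventions, and the places where a design
decision was genuinely open.

## Duplication-loss reconciliation

Given a rooted binary gene tree, a rooted binary species tree with
uniquely labelled nodes, and a leaf-to-species map, `lca_map()`
assigns each gene node to the last common ancestor (LCA) of its
descendant leaves' species. `label_events()` then labels an internal
gene node a **duplication (D)** when it maps to the same species node
as at least one of its children, and a **speciation (S)** otherwise.
Losses are read off species-tree path lengths: an S node at species
node *s* with a child mapped to *u* implies `pathlen(s, u) - 1`
losses; a D node implies `pathlen(s, u)` (the undated convention:
duplications happen "at" species nodes, and a duplicate lineage must
immediately survive the speciation at its own node). The weighted cost
is `c_d * duplications + c_l * losses`, defaults (1, 1).

LCA mapping is simultaneously optimal for duplications and losses
under this event model. We do not take that theorem on faith: the test
suite enumerates, for small instances, *every* valid mapping of gene
nodes to species nodes, counts events for each, and checks that the
LCA reconciliation attains the elementwise minimum. The same
enumeration backs `root_by_dl()`, which tries every branch of an
unrooted gene tree as a root position and keeps the cheapest; ties are
broken by a deterministic lexicographic rule on the leaf labels
flanking the candidate branch (input-order independence matters more
here than any particular winner, since co-optimal roots are all
reported).

This parsimony machinery is a desk-scale stand-in for
maximum-likelihood reconciliation software: the event vocabulary
(S/D/loss per node, per-edge losses) is identical, but no rates are
estimated and no numerical optimisation is involved, which is what
makes exhaustive oracle testing possible. Consequently no result
should be read as numerically reproducing an ML reconciler; agreement
is at the event-vocabulary level on unambiguous instances.
Gene-tree polytomies are resolved *randomly* (seeded), not
DL-optimally -- mirroring common practice of running an automatic
resolver before reconciliation -- and this is a documented limitation.
Viral or otherwise xenologous sequences can be handled the way the
motivating analyses do (assigning them to a host species) via the
leaf map; no transfer events are modelled.

## Ancestral complements

`copy_numbers()` turns a reconciliation into a per-species-node
lineage count N(s). The propagation convention is: **N(s) counts
lineages present at s after applying duplications mapped at s and
losses on the edge into s**; hence `N(origin) = 1 + duplications at
the origin` and N at each extant species equals its observed gene
count. Operationally, each gene-tree edge (u, v) contributes one
lineage to every species node on the path from M(u) to M(v),
*including* M(u) only when u is a duplication and *excluding* M(v)
only when v is a duplication (v's own children then cover M(v)). This
is the only convention consistent with leaf totals, and it satisfies
the edge-balance identity

> N(child) - N(parent) = duplications at child - losses on the edge
> into child

on every species edge *except* the edge into the family's origin,
where origination itself contributes the +1 (there the identity is
`N(origin) = 1 + D - L`). The tests enforce both forms.

Orthogroups are obtained by deleting duplication nodes from the gene
tree (optionally only duplications mapped at or above a chosen species
node) and taking the resulting components; groups are named from the
gene tokens of reference-species members, with deterministic
`unnamed-k` fallbacks. Presence/absence matrices are defined at the
orthogroup level, and a clade lacking a family due to inferred loss is
reported as 0, never as missing data.

## The synthetic-data generator

`simulate_family()` runs a linear birth-death process per gene lineage
along every species-tree edge (exponential waiting times; duplication
rate λ, loss rate μ, per-edge overrides), with speciation copying
every surviving lineage into both child edges. Defaults are λ = 0.5,
μ = 0.2 per unit branch length on a 12-taxon chordate tree of depth
2.2 -- moderate turnover producing families of roughly one to a few
dozen genes, the regime of the ligand/receptor families that motivate
the package. Extinct sublineages are pruned from the emitted gene tree
(so observed trees look like real data) but retained in the event log.

Because parsimony cannot see masked events (e.g. a duplication whose
one copy later dies out), the simulator's *raw* event counts are not
the right oracle for ancestral complements. `replay_complement()`
therefore replays the **observable** part of the truth: lineages with
surviving descendants, with each surviving duplication attributed to
the species LCA of its surviving descendant species. It computes
counts by a different route than `copy_numbers()` (top-down
propagation of per-node event tallies over the species tree, from the
simulator's internal lineage records, versus per-gene-edge interval
coverage on the reconciled tree), so exact agreement between the two
is a meaningful two-sided check, and it holds exactly on every
simulated family in the suite. The raw logs remain available and back
the weaker one-sided checks (with μ = 0, inferred duplications equal
logged duplications exactly; with μ > 0, parsimony never overcounts).

`simulate_similarity()` emulates an all-vs-all BLAST network. Within a
family the score (-log10 P) is `intercept - slope * patristic
distance + N(0, noise_sd)`, floored at 0 (defaults 40, 2, 2). Between
families, P-values follow the chance-alignment null -- the number of
spurious local alignments at P ≤ x is Poisson with mean x -- rescaled
so the typical between-family score is `cross_family_mean` (default
4): `P = 10^(-cross_family_mean) * Exp(1)`. The choice of the null
rather than a Gaussian score for unrelated pairs is deliberate: a
Gaussian tail at these defaults would let roughly one chance edge per
thousand unrelated pairs cross a P = 1e-10 threshold, merging true
families in most simulations, which is not how local-alignment
statistics behave; under the null such crossings are ~1e-6 events.
`noise_sd` applies only to within-family scores, where alignment
quality genuinely jitters. The generator does *not* emulate divergent
true homologs that connect only through intermediates, compositional
bias, or profile effects -- so a green clustering test establishes
correct graph algorithms on a well-separated world, not robustness of
cluster delineation on hard real data.

Bootstrap replicates are emulated by seeded random
nearest-neighbour interchanges (`perturb_tree()`); real replicates
from re-inference can be supplied instead wherever a replicate list is
accepted.

## Similarity clustering

Clusters are connected components of the similarity graph at a
P-value threshold, with **P ≤ t inclusive** (so printed threshold
ladders reproduce exactly). Asymmetric BLAST pairs collapse to the
most significant P by default (min; configurable to max/mean), and
E-values are used as P surrogates after capping at 1 -- the
distinction does not affect thresholded topology.
`merge_threshold()` returns the bottleneck (minimax) edge P over all
paths between two vertex sets, computed by Kruskal-style union-find;
the tests compare it against a literal threshold-sweep. Partitions
along a ladder are provably nested; the tests check the containment
relation pairwise anyway. The 2D layout is a plain force-directed
relaxation, seeded and deterministic; its constants are module
defaults, documented as such, and nothing downstream consumes layout
geometry.

## Branch support

`tbe()` implements Transfer Bootstrap Expectation: for each internal
reference branch with lighter side p, the transfer index δ against a
replicate is the minimum, over replicate branches, of the
orientation-minimal Hamming distance between membership vectors,
capped at p - 1 (the cap is what trivial branches achieve); support is
the mean of `1 - δ/(p-1)` over replicates. `fbp()` is the classical
bootstrap proportion (δ = 0 fraction). Ultrafast bootstrap values are
an inference-time quantity and cannot be recomputed from replicate
trees alone; FBP over supplied replicates is the documented stand-in
for the "circle" values in figure-style summaries. Bipartition
comparison is exact and quadratic in branches -- fine at desk scale; a
linear-time transfer-index algorithm exists and is noted as an
optimisation, not a need. The traffic-light bands of
`classify_support()` (high ≥ 0.90, intermediate ≥ 0.70) are module
configuration, not published constants, and are applied per metric
since TBE and resampling proportions are not on comparable scales.

## Sequence filters

`scan_cysteine_motif()` encodes the standard chemokine nomenclature on
the first two cysteines of the N-terminal window (gap 0 → CC, 1 →
CXC, 3 → CX3C; a single cysteine → XC; anything else → none). The
window (60 residues) and offset (0; set it to a signal-peptide length
to scan the mature peptide) are explicit parameters because the
precursor-vs-mature question is genuinely open in practice; the
classification is exhaustive and mutually exclusive by construction.
The transmembrane filter keeps candidates with 5-8 predicted helices
(inclusive) -- the GPCR-candidate window allowing for missed or split
helices -- and rejects missing predictions with an explicit reason.
Length outliers are flagged with a **robust z-score**
(median/MAD): a classical mean/SD z is bounded by (n-1)/√n and can
never flag the one grossly long sequence in a group of four, which is
exactly the situation the rule exists for. All flags are advisory;
nothing is silently dropped.

## Determinism and the pipeline

All randomness flows from explicit integer seeds; the pipeline derives
per-stage seeds from one master seed and records them in its JSON
manifest along with an md5 checksum per output file. No output
carries timestamps, so identical config + seed reproduces identical
checksums -- enforced as an acceptance criterion. Stage failures abort
with the stage named; outputs written before the failure stay on disk
and the manifest marks the failed stage.

## Known limitations

* Parsimony reconciliation with unit weights, not ML; no transfer
  events; no dated (branch-length-aware) reconciliation.
* Random polytomy resolution can inflate duplication counts relative
  to an optimal resolution.
* The similarity generator's families are well separated by
  construction; it produces no amino-acid sequences.
* NNI perturbation is a topology-noise model, not a bootstrap: TBE/FBP
  values on synthetic replicates characterise the support machinery,
  not any inference method.
* The bundled species tree is a synthetic reconstruction of
  uncontroversial chordate relationships for examples and simulation,
  not a data product.
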