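---
title: "Designing oligo pools as computation graphs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing oligo pools as computation graphs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligopool)
```

## The model

A sequence library is represented as a directed acyclic graph of
*pools* (collections of sequences) produced by *operations* (the steps
that create them). Operations fall into four categories: sources
(`from_seq`, `from_seqs`, `from_pwm`, `from_iupac`, `random_kmers`),
transformations (`mutagenize`, `mutagenize_orf`, `delete_scan`, `flip`,
`shuffle_region`, `recombine`, `get_barcodes`, `stylize`, `edit_seq`,
`insert_at`, `insert_multiscan`), compositions (`join_pools`,
`stack_pools`), and state operations (`select_states`, `reorder_states`,
`filter_pool`, `repeat_pool`).

The central idea is exact integer indexing. Every pool of cardinality
$N$ indexes its members by states $s \in \{0, \dots, N-1\}$, and each
operation owns a bijection between its output states and the tuple
(internal state, input states):

* **Product layouts.** For most operations the output space is the
  Cartesian product of the operation's own variants and its inputs'
  states. The bijection is mixed-radix decomposition: the internal
  state is the least significant digit, inputs follow in declaration
  order with increasing significance. This digit order is a convention
  we fix and document (any fixed bijection works); it makes consecutive
  states enumerate an operation's own variants before advancing a
  parent, so "all variants of parent 0" are contiguous.
* **Union layouts.** `stack_pools` lays its inputs' states out
  consecutively; a state selects exactly one branch and inactive
  branches receive nothing.
* **Diagonal layouts.** `get_barcodes` keeps the received state *and*
  forwards it unchanged: its cardinality equals its parent's, but the
  barcode is a function of the overall state. This is a bijection
  trivially and keeps barcode uniqueness compatible with lazy
  evaluation (below).
* **Remap layouts.** `select_states`, `reorder_states`, and
  `filter_pool` map output state $i$ to a stored parent state.

Generation is lazy. `pool_size()` is computed purely from this algebra
— an instrumented test verifies that no sequence is ever constructed by
a size query — so arbitrarily many candidate designs can be compared
before any sequence exists. `generate(pool, s, master_seed)` then runs
a backward pass (the state is decomposed down the graph; inactive stack
branches get no state) fused with a forward pass (each operation builds
its output from its internal state and its inputs' sequences).

All state arithmetic is exact. Values below $2^{53}$ are carried as
integer-valued doubles; beyond that the package switches to an internal
arbitrary-precision integer (base-$10^6$ digit vectors with compare,
add, subtract, multiply, and divmod), since products of a few
mutagenesis pools overflow 64-bit integers easily. No installed package
provides this primitive, and it is small, so it is implemented here and
tested against double arithmetic below $2^{53}$ and against algebraic
identities above it.

## Reproducible randomness

Random-mode operations must declare a sample count — all state spaces
are finite, so sizes are always available in O(graph). Each random
draw stream is seeded by a stable hash of (master seed, node id,
internal state, purpose tag). Node ids are derived from the DAG
structure (kind, parameters, input ids), never from runtime memory
identity, so the same design file yields byte-identical libraries
across processes. A consequence worth knowing: two structurally
identical sibling subtrees share an id and therefore draw identically —
that is the correct reading of "generation is a pure function of the
structure", and distinct behavior is obtained by giving the siblings
distinct parameters or prefixes.

`generate()` saves and restores the caller's RNG state, and purity is
tested by re-generating shuffled state ranges after perturbing the
global RNG.

## Tagged sequences and coordinates

Sequences carry named regions written as XML-style tags
(`AAA<cre>CCCGGG</cre>TTT`, self-closing anchors `ACGT<ins/>ACGT`).
**All coordinates are 0-based half-open**, one convention everywhere;
design-card residue positions are 1-based, matching how protein
positions are reported.

Edits are defined by a target interval and a replacement; with
$\delta = |\text{replacement}| - |\text{target}|$, a region strictly
right of the edit shifts by $\delta$, a region containing the edit
stretches by $\delta$, and a zero-length anchor at an insertion point
grows over the inserted text, which is what lets serial operations keep
addressing the same region. Edits that partially cross a region
boundary are errors: there is no published semantics for splitting a
region, and failing loudly is safer than guessing. The shift rules are
property-tested against an independent oracle that marks every
character with its region memberships, edits the character vector, and
reads coordinates back from the marks — no shift arithmetic in the
oracle.

Styles (foreground, background, bold, underline) are carried per
character as ordered overlays, later overlays winning attribute-wise,
so a mutated position can be underlined inside a region that is already
shaded. An equal-length substitution is treated as modifying characters
in place — their styles persist under the new overlay — while
length-changing edits leave inserted characters unstyled. Rendering
emits one ANSI escape pair per same-style run, and stripping escapes
recovers the characters exactly.

## Operation-specific choices

* **Enumeration orders** (fixed, documented, otherwise arbitrary):
  nucleotide substitutes in `A < C < G < T` order minus the current
  base; substitute residues in alphabetical single-letter order
  excluding the wild type; position pairs lexicographic; IUPAC
  expansions mixed-radix with the leftmost position least significant.
* **Codon policy.** `missense_only_first` chooses the most frequent
  codon encoding the substitute residue from the usage table (packaged
  human table, overridable), so an emitted codon always translates to
  the intended residue and never the wild type. Default eligible
  positions exclude an initial ATG and a terminal stop.
* **Random codon mutagenesis** keeps zero-mutation draws (each position
  mutates independently with the stated rate; resampling empty draws
  would bias the per-position marginal).
* **Geometry is measured at build time** from the parent's state-0
  sequence (region bounds, reading frame, wild-type codons), so
  cardinalities never require generation; each constructed state
  re-validates the span length and fails with node and state context if
  an upstream operation made the geometry state-dependent.
* **Barcodes.** Lazy per-state generation cannot consult global
  "already used" bookkeeping, so `get_barcodes` maps the overall state
  through a seeded bijective affine permutation $s \mapsto (as+b) \bmod
  4^L$ (with $a$ odd) and base-4 encodes the result. Injectivity
  guarantees pairwise-distinct barcodes across the whole pool.
* **Multi-site scans.** `insert_multiscan` consumes its site pools by
  internal sampling (cardinality = declared sample count), not by state
  digits — the published example counts are only consistent with that
  reading — and places sites by equal-length substitution inside the
  target region, drawing placements by rejection until pairwise
  disjoint (bounded by `max_rejections`, then an error naming the
  state). Substitution rather than insertion keeps the region length
  fixed, which is what overlap avoidance presupposes.
* **Filtering** is the one eager operation: its cardinality requires
  evaluating the predicate, so the kept-state index is materialized at
  the first size query and cached, with the parent evaluated under a
  dedicated `materialize_seed`. The cost is documented rather than
  hidden, and filters of random-mode parents are exact only at that
  seed.

## Names and design cards

Prefixed operations contribute `prefix_<internal state>` tokens
(zero-padded to `max(2, digits(cardinality - 1))`); stacks contribute
their branch label as a bare token. Tokens are joined with `.` in
depth-first, upstream-before-downstream order along the active path, so
a wild-type replicate with mutation variant 3 and barcode 1 is named
like `wt.mut_03.bc_01`. Unprefixed pools fall back to `s<state>`. Name
injectivity over all states is part of the test suite.

Design cards record tracked variables qualified by prefix (or kind),
e.g. `mut.positions`. Operations on inactive stack branches contribute
nulls rather than being omitted, so `compile_cards()` always returns a
rectangular table usable directly as covariates — the same prefix on
*different* branches deliberately merges into shared columns, while a
duplicate prefix on one path is a configuration error.

## The packaged examples

`build_gb1()` reconstructs a deep-mutational-scanning design for the
56-residue GB1 domain: 100 wild-type replicates, all 1,045 single and
536,085 pairwise amino-acid substitutions over the 55 eligible
positions, and 10,000 random higher-order variants at 10% per-position
rate — 547,230 sequences. The coding sequence is the most-frequent-
codon encoding of the canonical GB1 protein; every printed count
depends only on the 55 eligible positions.

`build_mpra()` reconstructs a regulatory-grammar MPRA design: three
consensus-like synthetic TFBS motifs (labeled HNF4A, PPARA, XBP1, each
styled a distinct color and flipped to both orientations) are
multiscan-inserted 10,000 times into a synthetic inert 100-bp CRE,
replicated three times, and barcoded — 30,000 sequences with 30,000
distinct barcodes.

`build_splice()` builds a cryptic donor-site insertion library: 9-mers
sampled from a packaged 5' splice-site PWM (consensus CAG|GTAAGT, GT
invariant), deduplicated, scored by a pluggable strength scorer
(default: PWM log-odds — the scorer interface is the extension point
for external strength models), cut into 100 equal-count score-rank
bins, 20 drawn per bin (2,000 distinct 9-mers), inserted at 50 exonic
and 50 intronic offsets flanking the canonical site of a synthetic
exon/intron junction, each paired with a control disrupted at +2
(T>A). Cards record strength, offset, and branch. The default PWM
sample count (50,000) was chosen from the exactly computed expected
number of distinct 9-mers under the packaged PWM (~4,600), which must
exceed the 2,000 needed for 20 unique draws per bin; sampling is
deduplicated before binning precisely so the retained set is distinct.
Bins are equal-count by score *rank*; ties are broken by sampling
order, which is deterministic under the master seed.

## What the synthetic fixtures do and do not show

The packaged ORF, CRE, motifs, PWM, and junction are synthetic
stand-ins chosen to be realistic in length, composition, and
information content. Tests on them demonstrate the combinatorial,
coordinate, naming, and reproducibility contracts of the framework —
they do not validate biological activity of any sequence, and the
splice example's log-odds scorer is a strength *interface*, not a
splicing model. Problem sizes used by the test suite (full enumeration
of the 547,230-sequence DMS design, all 30,000 MPRA members, 50,000 PWM
draws) were chosen so the whole suite runs comfortably on one CPU.

## Known limitations

* Region styling under `shuffle_region` follows positions, not
  characters.
* `recombine` takes regions and styles from parent A.
* Geometry-from-state-0 assumes upstream operations keep region
  lengths state-independent (violations fail loudly at generation).
* `filter_pool` requires an enumerable parent (≤ 10^6 states) and is
  eager by necessity.
* Design files cannot serialize arbitrary filter predicates.
* Sequence optimization, synthesis-constraint checking, and primer
  design are out of scope.
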