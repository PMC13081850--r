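# oligopool

Declarative, lazily evaluated design of DNA oligonucleotide libraries
in R.

Designed oligo pools are the raw material of multiplex assays of
variant effect — deep mutational scanning (DMS) libraries that
enumerate amino-acid substitutions of a protein, MPRA libraries that
arrange transcription-factor binding sites across regulatory elements,
barcoded reporter pools, and in silico perturbation libraries for
probing genomic AI models. Writing one-off scripts for the
combinatorial bookkeeping these designs require is tedious and
error-prone. `oligopool` replaces the scripts with a composable
framework for the scientists who build such libraries.

## The core idea

A library is a directed acyclic graph of **pools** (collections of
sequences) connected by **operations** (mutagenesis, insertion,
barcoding, concatenation, stacking, ...). Every pool of cardinality
*N* indexes its members by integer states *s* ∈ {0, …, N−1}, and every
operation owns an exact bijection between output states and (internal
state, input states):

* Cartesian-product spaces use **mixed-radix decomposition**
  (internal state least significant, inputs in declaration order);
* pool-merging uses a **disjoint union** (a state selects one branch;
  inactive branches receive nothing).

Generation is lazy: `pool_size()` is pure state algebra, so candidate
designs can be compared before a single sequence exists, and
`generate(pool, s, master_seed)` is a pure function — the sequence, its
automatic name (e.g. `wt.mut_03.bc_01`), and its **design card** (the
tracked construction parameters, ready to be downstream covariates)
are reproducible for any state in any order, in any process. State
arithmetic is exact at any size (arbitrary-precision beyond 2^53).

Sequences carry named regions written as XML-style tags
(`AAA<cre>CCCGGG</cre>TTT`, anchors `ACGT<ins/>ACGT`) that stay valid
through content-changing edits, plus per-character styling rendered
with ANSI escapes for terminal auditing. All coordinates are 0-based
half-open.

## A worked example

A toy design: wild-type replicates stacked with a deletion scan over a
tagged region.

```r
library(oligopool)
src <- from_seq("AAA<tag>CCCGGG</tag>TTT")
dms <- stack_pools(
  wt  = repeat_pool(src, 2, prefix = "rep"),
  del = delete_scan(from_seq("AAA<tag>CCCGGG</tag>TTT"), "tag",
                    window = 3, prefix = "del"))
print_dag(dms)
#> [1] from_seqs        mode=sequential size=1
#> [2] repeat           mode=sequential size=2  inputs=[1]
#> [3] from_seqs        mode=sequential size=1
#> [4] delete_scan      mode=sequential size=4  inputs=[3]
#> [5] stack            mode=fixed      size=6  inputs=[2,4]  <- root
pool_size(dms)
#> [1] 6
print_library(dms, n = 4, plain = TRUE)
#> wt.rep_00   AAACCCGGGTTT
#> wt.rep_01   AAACCCGGGTTT
#> del.del_00  AAAGGGTTT
#> del.del_01  AAACGGTTT
compile_cards(dms)
#> # A tibble: 6 × 6
#>   name       sequence     stack.component rep.replicate del.del_start del.window
#> 1 wt.rep_00  AAACCCGGGTTT wt              0             <NA>          <NA>
#> 2 wt.rep_01  AAACCCGGGTTT wt              1             <NA>          <NA>
#> 3 del.del_00 AAAGGGTTT    del             <NA>          0             3
#> 4 del.del_01 AAACGGTTT    del             <NA>          1             3
#> 5 del.del_02 AAACCGTTT    del             <NA>          2             3
#> 6 del.del_03 AAACCCTTT    del             <NA>          3             3
```

The size (6) is computed without generating anything; each row of the
card table says exactly how its sequence was built (branch, replicate
index, deletion window start), with nulls on the inactive branch's
columns.

Three full-scale example builders ship with the package:

* `build_gb1()` — a GB1-domain DMS design: 100 wild-type replicates +
  1,045 single + 536,085 pairwise amino-acid substitutions + 10,000
  random higher-order variants = **547,230 sequences**;
* `build_mpra()` — an MPRA regulatory-grammar design: three
  orientation-flipped TFBS pools multiscan-inserted 10,000 times into a
  100-bp CRE, ×3 replicates, each sequence distinctly barcoded =
  **30,000 sequences**;
* `build_splice()` — a cryptic 5′ splice-site insertion library:
  2,000 strength-binned donor 9-mers × 100 insertion offsets ×
  variant/control pairs.

`export_fasta()` / `export_cards()` write the library; YAML design
files (`build_from_design()`, `design_to_list()`) and a CLI
(`run_cli()`, `inst/cli/oligopool.R` — subcommands `build`, `inspect`,
`preview`, `example`, `validate`) make designs diffable and
reproducible end to end.

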