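# A small deep-mutational-scanning design: wild-type replicates stacked
# with all single-nucleotide variants of a tagged region.
master_seed: 0
root: root
nodes:
  - id: src
    op: from_seqs
    params:
      texts: ["AAAC<tag>GGGTTT</tag>CAT"]
  - id: wt
    op: "repeat"
    inputs: [src]
    params: {n: 3, prefix: rep}
  - id: snv
    op: mutagenize
    inputs: [src]
    params: {scheme: single, region: tag, prefix: mut}
  - id: root
    op: stack
    inputs: [wt, snv]
    params:
      labels: [wt, single]
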