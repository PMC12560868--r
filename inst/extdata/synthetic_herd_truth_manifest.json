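{
  "individuals": "inst/extdata/synthetic_herd_individuals.tsv",
  "loci": "inst/extdata/synthetic_herd_loci.tsv",
  "planted_roh": "inst/extdata/synthetic_herd_planted_roh.tsv",
  "counts": {
    "purebred": 16,
    "admixed": 4,
    "panel": 12,
    "planted_roh": 13
  }
}
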