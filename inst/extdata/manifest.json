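{
  "table3_gold_tap.tsv": {
    "rows": 36,
    "cols": 4,
    "md5": "f73341c655a2ce34f60d39273c5751aa"
  },
  "table4_silver_tap.tsv": {
    "rows": 36,
    "cols": 7,
    "md5": "051c96c67d069177e6b2ecfd17ee93e3"
  },
  "table5_composite_tap.tsv": {
    "rows": 4,
    "cols": 5,
    "md5": "14cdf7b41037e9810e6a1f887ef0781c"
  },
  "overlap_counts.tsv": {
    "rows": 2,
    "cols": 4,
    "md5": "6f09043f7c78f1899f209552b53a07b0"
  }
}
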