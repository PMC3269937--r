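comparison	n_gold	n_pred	n_overlap
gold48_vs_silver	1667	1813	528
nlm_vs_silver	179	NA	135
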