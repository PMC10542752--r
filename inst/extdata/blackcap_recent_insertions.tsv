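key	value
recent_copies	9404
recent_bp	10612698
pct_ltr_copies_recent	19.4
pct_ltr_cov_recent	31.0
raw_total_bp	80986987
raw_pct_genome	7.68
final_total_bp	53368488
final_pct_genome	5.06
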