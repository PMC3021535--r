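row	induced	non_induced
promoters_with_beaf_motif	3	69
promoters_bound_by_beaf	3	66
promoters_bound_with_motif	2	48
total_promoters	11	104
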