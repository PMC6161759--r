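name	value
n_90_99	20395
n_81_89	26585
n_71_80	13050
n_60_69	1738
n_50_59	357
n_40_49	253
n_30_39	93
n_len30	9
n_lt30	94
n_lt100	62565
pct_lt100_of_all	48.93
printed_pct_70_99_of_lt100	95.9
printed_n_le30	103
printed_pct_le30_of_lt100	0.16
printed_n_31_59	694
printed_pct_50_59_of_all	0.28
printed_pct_40_49_of_all	0.2
printed_pct_30_39_of_all	0.07
printed_pct_le30_of_all	0.08
n_second_release	71
n_excluded_sole_intron	16
n_excluded_primer_site	7
n_retained	48
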