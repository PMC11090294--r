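term	mean_square	f_value	pvalue_printed
Sex	14700000	689.47	NA
Generation	1320000	61.72	NA
gga1_168m	1510000	70.80	NA
gga1_171v	634000	29.65	NA
gga1_178v	56800	2.66	0.1032
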