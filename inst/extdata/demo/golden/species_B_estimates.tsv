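family	hits	mean_element_bp	coverage_fraction	copies_per_genome	genome_fraction	percent_of_genome	ci_low	ci_high
satA	4	600	0.2513766666666667	15	0.03	3	4	41
lineB	15	800	0.2513766666666667	59	0.15733333333333333	15.733333333333333	33	97
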