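family	hits	mean_element_bp	coverage_fraction	copies_per_genome	genome_fraction	percent_of_genome	ci_low	ci_high
satA	17	600	0.24949	68	0.136	13.600000000000001	40	108
lineB	6	800	0.24949	24	0.064	6.4	8	52
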