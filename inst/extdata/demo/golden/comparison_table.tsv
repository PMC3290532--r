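family	depth	copies_a	percent_a	copies_rollup_a	rollup_discrepancy_a	copies_b	percent_b	copies_rollup_b	rollup_discrepancy_b	ratio_a_over_b
All repetitive elements	0	92	20	92	FALSE	74	18.733333333333334	74	FALSE	1.07
satA	1	68	13.600000000000001	NA	FALSE	15	3	NA	FALSE	4.53
lineB	1	24	6.4	NA	FALSE	59	15.733333333333333	NA	FALSE	0.41
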