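canonical_motif	unit_len	n_runs	total_bp	complete_unit_bp	percent_bp	percent_complete_units	longest_bp
AAC	3	4	39	36	0.013	0.012	11
AAG	3	5	46	45	0.015333333333333332	0.015	10
AAT	3	17	156	153	0.052	0.051	10
AATT	4	2	24	24	0.008	0.008	12
AC	2	81	507	492	0.169	0.164	9
ACG	3	2	20	18	0.006666666666666667	0.006	11
ACT	3	4	39	36	0.013	0.012	10
AG	2	79	494	482	0.16466666666666666	0.16066666666666668	8
AGAT	4	1	12	12	0.004	0.004	12
AGC	3	1	9	9	0.003	0.003	9
AGT	3	5	47	45	0.015666666666666666	0.015	11
AT	2	448	2899	2790	0.9663333333333334	0.93	12
ATC	3	2	19	18	0.006333333333333333	0.006	10
ATG	3	2	18	18	0.006	0.006	9
ATT	3	12	115	108	0.03833333333333333	0.036	11
ATTT	4	1	14	12	0.004666666666666667	0.004	14
CCT	3	1	10	9	0.0033333333333333335	0.003	10
CG	2	31	191	188	0.06366666666666666	0.06266666666666666	8
CGT	3	1	9	9	0.003	0.003	9
CT	2	77	485	472	0.16166666666666665	0.15733333333333333	9
CTT	3	4	36	36	0.012	0.012	9
CTTG	4	1	14	12	0.004666666666666667	0.004	14
GGT	3	1	9	9	0.003	0.003	9
GGTT	4	1	12	12	0.004	0.004	12
GT	2	79	495	478	0.165	0.15933333333333333	8
GTT	3	2	18	18	0.006	0.006	9
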