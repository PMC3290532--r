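canonical_motif	unit_len	n_runs	total_bp	complete_unit_bp	percent_bp	percent_complete_units	longest_bp
AAAT	4	2	30	28	0.01	0.009333333333333334	17
AAC	3	1	9	9	0.003	0.003	9
AACT	4	1	12	12	0.004	0.004	12
AAG	3	5	48	45	0.016	0.015	11
AAT	3	14	133	126	0.044333333333333336	0.042	10
AC	2	63	408	394	0.136	0.13133333333333333	9
ACC	3	1	9	9	0.003	0.003	9
ACT	3	3	28	27	0.009333333333333334	0.009	10
AG	2	93	593	568	0.19766666666666666	0.18933333333333333	9
AGC	3	1	9	9	0.003	0.003	9
AGG	3	1	10	9	0.0033333333333333335	0.003	10
AGT	3	3	28	27	0.009333333333333334	0.009	10
AT	2	395	2549	2458	0.8496666666666667	0.8193333333333334	11
ATC	3	2	18	18	0.006	0.006	9
ATCT	4	1	12	12	0.004	0.004	12
ATG	3	3	27	27	0.009	0.009	9
ATT	3	25	235	228	0.07833333333333334	0.076	14
CCT	3	1	9	9	0.003	0.003	9
CG	2	39	238	238	0.07933333333333334	0.07933333333333334	8
CGT	3	2	19	18	0.006333333333333333	0.006	10
CT	2	76	488	474	0.16266666666666665	0.158	10
CTT	3	5	47	45	0.015666666666666666	0.015	10
GT	2	80	514	492	0.17133333333333334	0.164	9
GTT	3	3	27	27	0.009	0.009	9
GTTT	4	1	13	12	0.004333333333333333	0.004	13
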