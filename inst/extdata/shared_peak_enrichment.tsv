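shared_datasets	n_genes	n_ieg_genes	n_tss	n_ieg_tss	odds_ratio	p_value
1-8	8785	204	102496	913	NA	NA
2-8	5270	171	71384	853	6.3	2.2e-16
3-8	2882	128	45360	751	5.9	2.2e-16
4-8	1304	86	24616	590	5.9	2.2e-16
5-8	507	56	11528	433	7.4	2.2e-16
6-8	182	35	4896	299	10.3	2.2e-16
7-8	42	13	1376	124	12.6	2.2e-16
8	8	5	264	18	8.3	4.6e-11
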