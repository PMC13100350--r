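chr1	6000	6300	atac_peak_1	120	.	12.5	4.0	3.0	150
chr1	10500	10800	atac_peak_2	200	.	25.1	6.2	4.5	140
chr1	33900	34200	atac_peak_3	90	.	8.3	2.5	1.7	160
chr1	36000	36250	atac_peak_4	45	.	4.1	2.8	2.1	120
chr2	4000	4300	atac_peak_5	150	.	18.0	5.0	3.6	155
chr2	8000	8200	atac_peak_6	30	.	2.0	0.8	0.05	-1
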