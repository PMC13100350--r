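chr1	12000	12040	pop_peak_1	55	.	1.2e-06
chr1	15000	15030	pop_peak_2	40	.	3.5e-05
chr1	31000	31050	pop_peak_3	60	.	8.0e-07
chr1	16000	16035	pop_peak_6	30	.	2.1e-05
chr2	5200	5240	pop_peak_4	35	.	4.2e-05
chr2	5600	5650	pop_peak_5	20	.	0.45
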