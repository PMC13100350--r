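chr1	toy	gene	10001	20000	.	+	.	gene_id "G1";
chr1	toy	transcript	10001	20000	.	+	.	gene_id "G1"; transcript_id "G1.t1"; transcript_biotype "protein_coding";
chr1	toy	transcript	10001	18000	.	+	.	gene_id "G1"; transcript_id "G1.t2"; transcript_biotype "retained_intron";
chr1	toy	gene	30001	34000	.	-	.	gene_id "G2";
chr1	toy	transcript	30001	34000	.	-	.	gene_id "G2"; transcript_id "G2.t1"; transcript_biotype "protein_coding";
chr1	toy	transcript	30001	33000	.	-	.	gene_id "G2"; transcript_id "G2.t2"; transcript_biotype "nonsense_mediated_decay";
chr1	toy	transcript	30501	34000	.	-	.	gene_id "G2"; transcript_id "G2.t3"; transcript_biotype "retained_intron";
chr2	toy	gene	5001	6000	.	+	.	gene_id "G3";
chr2	toy	transcript	5001	6000	.	+	.	gene_id "G3"; transcript_id "G3.t1"; transcript_biotype "lncRNA";
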