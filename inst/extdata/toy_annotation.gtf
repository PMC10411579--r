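chr1	braker	gene	100	900	.	+	.	gene_id "g1";
chr1	braker	transcript	100	500	.	+	.	gene_id "g1"; transcript_id "g1.t1";
chr1	braker	exon	100	200	.	+	.	gene_id "g1"; transcript_id "g1.t1";
chr1	braker	CDS	120	200	.	+	0	gene_id "g1"; transcript_id "g1.t1";
chr1	braker	transcript	600	900	.	+	.	gene_id "g1"; transcript_id "g1.t2";
chr1	braker	exon	600	900	.	+	.	gene_id "g1"; transcript_id "g1.t2";
chr2	braker	gene	50	800	.	-	.	gene_id "g2";
chr2	braker	transcript	50	400	.	-	.	gene_id "g2"; transcript_id "g2.t1";
chr2	braker	exon	50	400	.	-	.	gene_id "g2"; transcript_id "g2.t1";
chr2	braker	transcript	500	800	.	-	.	gene_id "g2"; transcript_id "g2.t2";
chr2	braker	exon	500	800	.	-	.	gene_id "g2"; transcript_id "g2.t2";
chr3	braker	gene	10	500	.	+	.	gene_id "g3";
chr3	braker	transcript	10	500	.	+	.	gene_id "g3"; transcript_id "g3.t1";
chr3	braker	exon	10	500	.	+	.	gene_id "g3"; transcript_id "g3.t1";
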