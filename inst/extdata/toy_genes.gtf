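chr1	toy	gene	10000	20000	.	+	.	gene_id "TOYG0001"; gene_name "TOYA"; gene_type "protein_coding";
chr1	toy	transcript	10000	20000	.	+	.	gene_id "TOYG0001"; transcript_id "TOYG0001.t1"; gene_name "TOYA"; gene_type "protein_coding";
chr1	toy	exon	10000	10500	.	+	.	gene_id "TOYG0001"; transcript_id "TOYG0001.t1"; gene_name "TOYA"; gene_type "protein_coding";
chr1	toy	exon	14000	15000	.	+	.	gene_id "TOYG0001"; transcript_id "TOYG0001.t1"; gene_name "TOYA"; gene_type "protein_coding";
chr1	toy	exon	19000	20000	.	+	.	gene_id "TOYG0001"; transcript_id "TOYG0001.t1"; gene_name "TOYA"; gene_type "protein_coding";
chr1	toy	CDS	14000	15000	.	+	0	gene_id "TOYG0001"; transcript_id "TOYG0001.t1"; gene_name "TOYA"; gene_type "protein_coding";
chr1	toy	CDS	19000	19500	.	+	0	gene_id "TOYG0001"; transcript_id "TOYG0001.t1"; gene_name "TOYA"; gene_type "protein_coding";
chr2	toy	gene	50000	60000	.	-	.	gene_id "TOYG0002"; gene_name "TOYB"; gene_type "protein_coding";
chr2	toy	transcript	50000	60000	.	-	.	gene_id "TOYG0002"; transcript_id "TOYG0002.t1"; gene_name "TOYB"; gene_type "protein_coding";
chr2	toy	exon	50000	50800	.	-	.	gene_id "TOYG0002"; transcript_id "TOYG0002.t1"; gene_name "TOYB"; gene_type "protein_coding";
chr2	toy	exon	54000	54600	.	-	.	gene_id "TOYG0002"; transcript_id "TOYG0002.t1"; gene_name "TOYB"; gene_type "protein_coding";
chr2	toy	exon	59000	60000	.	-	.	gene_id "TOYG0002"; transcript_id "TOYG0002.t1"; gene_name "TOYB"; gene_type "protein_coding";
chr2	toy	CDS	50200	50800	.	-	0	gene_id "TOYG0002"; transcript_id "TOYG0002.t1"; gene_name "TOYB"; gene_type "protein_coding";
chr2	toy	CDS	54000	54600	.	-	0	gene_id "TOYG0002"; transcript_id "TOYG0002.t1"; gene_name "TOYB"; gene_type "protein_coding";
chr2	toy	gene	30000	40000	.	+	.	gene_id "TOYG0003"; gene_name "TOYC"; gene_type "protein_coding";
chr2	toy	transcript	30000	40000	.	+	.	gene_id "TOYG0003"; transcript_id "TOYG0003.t1"; gene_name "TOYC"; gene_type "protein_coding";
chr2	toy	exon	30000	30500	.	+	.	gene_id "TOYG0003"; transcript_id "TOYG0003.t1"; gene_name "TOYC"; gene_type "protein_coding";
chr2	toy	exon	34000	34800	.	+	.	gene_id "TOYG0003"; transcript_id "TOYG0003.t1"; gene_name "TOYC"; gene_type "protein_coding";
chr2	toy	exon	39000	40000	.	+	.	gene_id "TOYG0003"; transcript_id "TOYG0003.t1"; gene_name "TOYC"; gene_type "protein_coding";
chr2	toy	CDS	34000	34800	.	+	0	gene_id "TOYG0003"; transcript_id "TOYG0003.t1"; gene_name "TOYC"; gene_type "protein_coding";
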