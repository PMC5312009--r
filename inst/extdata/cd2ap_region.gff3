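##gff-version 3
# Human chr6 CD2AP region (GRCh38 coordinates, gene spans approximate),
# the worked example for the four nested candidate-nomination criteria:
# index SNP rs9349407 (chr6:47,520,026, intronic in CD2AP).
6	ensembl_havana	gene	47231533	47309884	.	+	.	ID=ENSG00000146072;Name=TNFRSF21;biotype=protein_coding
6	ensembl_havana	gene	47477745	47627263	.	+	.	ID=ENSG00000198087;Name=CD2AP;biotype=protein_coding
6	ensembl_havana	gene	47652230	47671369	.	+	.	ID=ENSG00000153292;Name=ADGRF2;biotype=protein_coding
6	ensembl_havana	gene	47677423	47708510	.	-	.	ID=ENSG00000153294;Name=ADGRF4;biotype=protein_coding
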