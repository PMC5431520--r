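# Synonym table mapping common mitochondrial gene labels onto the
# controlled vocabulary (see mt_gene_vocabulary()). Matching is
# case-insensitive; tRNA synonyms use the three-letter amino acid code.
synonym	name
COI	cox1
COX1	cox1
CO1	cox1
COII	cox2
COX2	cox2
CO2	cox2
COIII	cox3
COX3	cox3
CO3	cox3
COB	cytb
CYB	cytb
CYTB	cytb
ATP6	atp6
ATPASE6	atp6
ATP8	atp8
ATPASE8	atp8
ND1	nad1
NADH1	nad1
ND2	nad2
NADH2	nad2
ND3	nad3
NADH3	nad3
ND4	nad4
NADH4	nad4
ND4L	nad4L
NADH4L	nad4L
ND5	nad5
NADH5	nad5
ND6	nad6
NADH6	nad6
12S	rrnS
12S rRNA	rrnS
s-rRNA	rrnS
rrn12	rrnS
small subunit ribosomal RNA	rrnS
16S	rrnL
16S rRNA	rrnL
l-rRNA	rrnL
rrn16	rrnL
large subunit ribosomal RNA	rrnL
tRNA-Ala	trnA
tRNA-Cys	trnC
tRNA-Asp	trnD
tRNA-Glu	trnE
tRNA-Phe	trnF
tRNA-Gly	trnG
tRNA-His	trnH
tRNA-Ile	trnI
tRNA-Lys	trnK
tRNA-Leu1	trnL1
tRNA-Leu(CUN)	trnL1
tRNA-Leu2	trnL2
tRNA-Leu(UUR)	trnL2
tRNA-Met	trnM
tRNA-Asn	trnN
tRNA-Pro	trnP
tRNA-Gln	trnQ
tRNA-Arg	trnR
tRNA-Ser1	trnS1
tRNA-Ser(AGN)	trnS1
tRNA-Ser2	trnS2
tRNA-Ser(UCN)	trnS2
tRNA-Thr	trnT
tRNA-Val	trnV
tRNA-Trp	trnW
tRNA-Tyr	trnY
FORF	F-orf
F-ORF	F-orf
MORF	M-orf
M-ORF	M-orf
M-ORF2	M-orf2
HORF	H-orf
H-ORF	H-orf
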