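# Default Duffy (FY) allele configuration: the three common ACKR1 alleles
# defined by a 15-base motif over exonic/promoter diagnostic positions
# (5' to 3'). Intronic and synonymous variation is ignored by design.
#
# SYNTHETIC COORDINATES: only the first two positions carry their real
# GRCh38 genomic coordinates (c.-67 GATA box = rs2814778 at
# chr1:159,204,893; c.125 Fya/Fyb = rs12075 at chr1:159,205,564). The
# remaining 13 exonic positions are internally consistent placeholders
# (reference bases taken from the motif suffix shared by all three
# alleles); replace them with curated coordinates before classifying real
# GRCh38 data at those positions. Motif-based classification (classify_motif)
# never depends on the placeholder coordinates.
#
# record	pos/name	label/motif	ref
position	159204893	c.-67	T
position	159205564	c.125	G
position	159205604	c.165	C
position	159205644	c.205	C
position	159205684	c.245	G
position	159205724	c.285	C
position	159205764	c.325	G
position	159205804	c.365	C
position	159205844	c.405	C
position	159205884	c.445	G
position	159205924	c.485	C
position	159205964	c.525	G
position	159206004	c.565	G
position	159206044	c.605	G
position	159206084	c.645	C
allele	FY*01	TGCCGCGCCGCGGGC
allele	FY*02	TACCGCGCCGCGGGC
allele	FY*02N.01	CACCGCGCCGCGGGC
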