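# Approximate hg38 coordinates of well-characterised human imprinted DMRs.
# BED6+2: chrom start end name score strand germline_origin notes
# Replace with a curated registry for production use; coordinates here are
# rounded locus-level approximations intended for registry-based QC demos.
chr11	1999000	2003000	H19_IGF2_ICR	0	.	paternal	H19/IGF2 imprinting control region
chr11	2698500	2701500	KCNQ1OT1_KvDMR1	0	.	maternal	KvDMR1
chr14	100810000	100818000	MEG3_IG_DMR	0	.	paternal	DLK1/MEG3 intergenic DMR
chr15	24954000	24958000	SNRPN_DMR	0	.	maternal	PWS imprinting centre
chr15	23565000	23568000	MKRN3_DMR	0	.	maternal	MKRN3 promoter DMR
chr19	56837000	56841000	PEG3_DMR	0	.	maternal	PEG3 promoter DMR
chr6	144006000	144009000	PLAGL1_DMR	0	.	maternal	PLAGL1/ZAC1 DMR
chr7	130490000	130494000	MEST_DMR	0	.	maternal	MEST/PEG1 promoter DMR
chr7	50781000	50785000	GRB10_DMR	0	.	maternal	GRB10 DMR
chr20	37519000	37523000	NNAT_DMR	0	.	maternal	NNAT promoter DMR
chr7	94655000	94659000	PEG10_DMR	0	.	maternal	PEG10/SGCE DMR
chr13	48318000	48322000	RB1_CpG85	0	.	maternal	RB1 intragenic CpG island
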