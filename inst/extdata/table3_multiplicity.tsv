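gene_id	description	n_total	n_up	n_down	diff
PTEN	phosphatase and tensin homolog	12	8	4	4
TNRC6B	trinucleotide repeat containing 6b	10	9	1	8
CPEB3	cytoplasmic polyadenylation element binding protein 3	9	7	2	5
TBL1XR1	transducin (beta)-like 1X-linked receptor 1	9	7	2	5
AAK1	AP2 associated kinase 1	9	8	1	7
SYNCRIP	synaptotagmin binding, cytoplasmic RNA interacting protein	8	7	1	6
ACSL4	acyl-CoA synthetase long-chain family member 4	8	7	1	6
CSNK1G1	casein kinase 1, gamma 1	8	7	1	6
SERTAD2	SERTA domain containing 2	8	7	1	6
ZFP148	zinc finger protein 148	7	5	2	3
ATXN1	ataxin 1	7	6	1	5
BCL2L2	BCL2-like 2	7	5	2	3
ZFP704	zinc finger protein 704	7	5	2	3
MBNL1	muscleblind-like 1 (Drosophila)	7	6	1	5
TMEM55B	transmembrane protein 55b	7	7	0	7
ELAVL2	ELAV (embryonic lethal, abnormal vision, Drosophila)-like 2	7	4	3	1
RICTOR	RPTOR independent companion of MTOR, complex 2	7	7	0	7
ACVR2A	activin receptor IIA	7	7	0	7
NUFIP2	nuclear fragile X mental retardation protein interacting protein 2	7	6	1	5
MIER3	mesoderm induction early response 1, family member 3	7	7	0	7
MECP2	methyl CpG binding protein 2	7	6	1	5
ZCCHC14	zinc finger, CCHC domain containing 14	6	6	0	6
AFF4	AF4/FMR2 family, member 4	6	4	2	2
TGFBR1	transforming growth factor, beta receptor I	6	5	1	4
DCX	doublecortin	6	5	1	4
CAMTA1	calmodulin binding transcription activator 1	6	4	2	2
TCF4	transcription factor 4	6	4	2	2
FBXO28	F-box protein 28	6	5	1	4
SMG1	SMG1 homolog, phosphatidylinositol 3-kinase-related kinase	6	6	0	6
RBM33	RNA binding motif protein 33	6	4	2	2
FUBP1	far upstream element (FUSE) binding protein 1	6	6	0	6
QK	quaking	6	5	1	4
UBE2D3	ubiquitin-conjugating enzyme E2D 3 (UBC4/5 homolog, yeast)	6	5	1	4
GSK3B	glycogen synthase kinase 3 beta	6	5	1	4
PHF17	PHD finger protein 17	6	5	1	4
IGF1R	insulin-like growth factor I receptor	6	4	2	2
SOX6	SRY-box containing gene 6	6	5	1	4
NR3C1	nuclear receptor subfamily 3, group C, member 1	6	3	3	0
NFAT5	nuclear factor of activated T-cells 5	6	5	1	4
NF1	neurofibromatosis 1	6	5	1	4
NAA50	N(alpha)-acetyltransferase 50, NatE catalytic subunit	6	6	0	6
MLL1	myeloid/lymphoid or mixed-lineage leukemia 1	6	4	2	2
SOX11	SRY-box containing gene 11	6	4	2	2
TRIM2	tripartite motif-containing 2	6	5	1	4
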