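feature	log2FC	padj	description
BCO1	1.61	3.32E-03	Beta-carotene oxygenase 1
BMP5	1.49	3.70E-02	Bone morphogenetic protein 5
CA10	1.33	2.53E-02	Carbonic anhydrase 10
CACHD1	0.99	2.11E-02	Cache domain containing 1
CCDC80	1.39	4.93E-02	Coiled-coil domain containing 80
CEMIP	1.29	2.71E-02	Cell migration-inducing hyaluronan-binding protein
CFH	1.95	2.40E-03	Complement factor H
COL12A1	1.34	4.80E-02	Collagen type XII alpha 1 chain
COL3A1	2.27	1.46E-03	Collagen type III alpha 1 chain
EDIL3	1.35	3.70E-02	EGF like repeats and discoidin domains 3
EDNRA	1.67	1.12E-02	Endothelin receptor type A
FIBIN	1.43	4.93E-02	Fin bud initiation factor homolog
FN1	1.41	1.84E-02	Fibronectin 1
FOXC1	1.88	1.56E-03	Forkhead box C1
GCNT1	1.68	1.96E-04	Glucosaminyl (N-acetyl) transferase 1, core 2
GDF10	1.52	7.71E-03	Growth differentiation factor 10
LINC01239	1.27	2.53E-02	Long intergenic non-protein coding RNA 1239
MITF	1.27	1.47E-02	Melanocyte inducing transcription factor
NPR3	1.59	2.71E-02	Natriuretic peptide receptor 3
RASSF9	1.86	2.05E-04	Ras association domain family member 9
SEMA3C	1.27	3.72E-02	Semaphorin 3C
SIX1	1.54	1.47E-02	SIX homeobox 1
SLCO1A2	1.16	7.71E-03	Solute carrier organic anion transporter family member 1A2
TBX18	1.78	3.32E-03	T-box 18
TFAP2A	1.58	4.93E-02	Transcription factor AP-2 alpha
TFAP2C	1.58	1.56E-03	Transcription factor AP-2 gamma
TM4SF1	2.14	1.71E-04	Transmembrane 4 L six family member 1
ZIC1	1.24	2.71E-02	Zic family member 1
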