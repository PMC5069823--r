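# Hand-transcribed case-matched variant calls: recurrently shared variants
# (per-case "mutated in >= 2 tumour sites" table) and the RAS hotspot allele
# fractions through the disease course. "WT"/0 cells are absent rows.
# Allele fractions not printed in the source tables are set to a nominal
# 30 %; printed fractions (all RAS rows; SMO of c06_pul_m1 is the de novo
# lung-lesion variant of the treatment table, protein change unspecified).
specimen_id	gene	hgvs_p	consequence	af_percent
c01_pt	KRAS	p.G12D	missense	55.59
c01_hep_s1	KRAS	p.G12D	missense	97.28
c01_pul_m1	KRAS	p.G12D	missense	16.77
c01_pt	TP53	p.R342*	nonsense	30
c01_pul_m1	TP53	p.R342*	nonsense	30
c02_pt	APC	p.Q1338*	nonsense	30
c02_hep_s1	APC	p.Q1338*	nonsense	30
c02_pul_s1	APC	p.Q1338*	nonsense	30
c02_pul_s2	APC	p.Q1338*	nonsense	30
c02_pt	KRAS	p.G12V	missense	53.59
c02_hep_s1	KRAS	p.G12V	missense	89.98
c02_pul_s1	KRAS	p.G12V	missense	47.32
c02_pul_s2	KRAS	p.G12V	missense	32.82
c02_pt	SMAD4	p.R361C	missense	30
c02_hep_s1	SMAD4	p.R361C	missense	30
c02_pul_s1	SMAD4	p.R361C	missense	30
c02_pul_s2	SMAD4	p.R361C	missense	30
c03_hep_m1	APC	p.R1450*	nonsense	30
c03_pul_m1	APC	p.R1450*	nonsense	30
c03_pul_m3	APC	p.R1450*	nonsense	30
c03_pt	APC	p.R876*	nonsense	30
c03_hep_m1	APC	p.R876*	nonsense	30
c03_pul_m1	APC	p.R876*	nonsense	30
c03_pul_m2	APC	p.R876*	nonsense	30
c03_pul_m3	APC	p.R876*	nonsense	30
c03_pt	KRAS	p.G12V	missense	21.92
c03_hep_m1	KRAS	p.G12V	missense	45.26
c03_pul_m2	KRAS	p.G12V	missense	21.22
c03_pul_m3	KRAS	p.G12V	missense	34
c03_hep_m1	PIK3CA	p.K111E	missense	30
c03_pul_m3	PIK3CA	p.K111E	missense	30
c03_pt	TP53	p.R196*	nonsense	30
c03_hep_m1	TP53	p.R196*	nonsense	30
c03_pul_m1	TP53	p.R196*	nonsense	30
c03_pul_m2	TP53	p.R196*	nonsense	30
c03_pul_m3	TP53	p.R196*	nonsense	30
c04_pt	TP53	p.R337C	missense	30
c04_hep_s1	TP53	p.R337C	missense	30
c04_hep_m1	TP53	p.R337C	missense	30
c04_pul_m1	TP53	p.R337C	missense	30
c04_pt	TP53	p.G199V	missense	30
c04_hep_s1	TP53	p.G199V	missense	30
c04_hep_m1	TP53	p.G199V	missense	30
c04_pul_m1	TP53	p.G199V	missense	30
c05_pt	APC	p.P1319Lfs*	frameshift	30
c05_hep_s1	APC	p.P1319Lfs*	frameshift	30
c05_pul_s1	APC	p.P1319Lfs*	frameshift	30
c05_pul_s2	APC	p.P1319Lfs*	frameshift	30
c05_pt	KRAS	p.G12A	missense	24.18
c05_hep_s1	KRAS	p.G12A	missense	9.7
c05_pul_s1	KRAS	p.G12A	missense	17.72
c05_pul_s2	KRAS	p.G12A	missense	36.04
c05_pt	PIK3CA	p.E542K	missense	30
c05_hep_s1	PIK3CA	p.E542K	missense	30
c05_pul_s1	PIK3CA	p.E542K	missense	30
c05_pul_s2	PIK3CA	p.E542K	missense	30
c05_pt	TP53	p.G244C	missense	30
c05_hep_s1	TP53	p.G244C	missense	30
c05_pul_s1	TP53	p.G244C	missense	30
c05_pul_s2	TP53	p.G244C	missense	30
c06_pt	APC	p.Q1367*	nonsense	30
c06_pul_m1	APC	p.Q1367*	nonsense	30
c06_pt	KRAS	p.G12V	missense	22.85
c06_pul_m1	KRAS	p.G12V	missense	26.73
c06_pt	SMAD4	p.Q250*	nonsense	30
c06_pul_m1	SMAD4	p.Q250*	nonsense	30
c06_pul_m1	SMO	p.?	other	30
c07_pt	TP53	p.V157F	missense	30
c07_hep_s1	TP53	p.V157F	missense	30
c07_hep_m1	TP53	p.V157F	missense	30
c07_hep_m2	TP53	p.V157F	missense	30
c07_pul_m1	TP53	p.V157F	missense	30
c08_pt	KRAS	p.G13D	missense	34.16
c08_hep_s1	KRAS	p.G13D	missense	50.44
c08_pul_s1	KRAS	p.G13D	missense	31.43
c08_pul_m1	KRAS	p.G13D	missense	12.85
c08_pt	TP53	p.R248Q	missense	30
c08_hep_s1	TP53	p.R248Q	missense	30
c08_pul_s1	TP53	p.R248Q	missense	30
c08_pul_m1	TP53	p.R248Q	missense	30
c09_pt	APC	p.R1114*	nonsense	30
c09_hep_s1	APC	p.R1114*	nonsense	30
c09_pul_m1	APC	p.R1114*	nonsense	30
c09_pul_m2	APC	p.R1114*	nonsense	30
c09_pul_m3	APC	p.R1114*	nonsense	30
c09_pt	TP53	p.R282W	missense	30
c09_hep_s1	TP53	p.R282W	missense	30
c09_pul_m1	TP53	p.R282W	missense	30
c09_pul_m2	TP53	p.R282W	missense	30
c09_pul_m3	TP53	p.R282W	missense	30
c10_pt	APC	p.T1556Nfs*	frameshift	30
c10_hep_m1	APC	p.T1556Nfs*	frameshift	30
c10_pul_m1	APC	p.T1556Nfs*	frameshift	30
c10_pt	FGFR3	p.P718S	missense	30
c10_hep_m1	FGFR3	p.P718H	missense	30
c10_pul_m1	FGFR3	p.P718S	missense	30
c10_pt	TP53	p.V157G	missense	30
c10_hep_m1	TP53	p.V157G	missense	30
c10_pul_m1	TP53	p.V157G	missense	30
c11_pt	TP53	p.R273C	missense	30
c11_hep_s1	TP53	p.R273C	missense	30
c11_pul_m1	TP53	p.R273C	missense	30
c11_pul_m2	TP53	p.R273C	missense	30
c12_hep_s1	APC	p.L1488Tfs*	frameshift	30
c12_pul_m1	APC	p.L1488Tfs*	frameshift	30
c12_pul_m2	APC	p.L1488Tfs*	frameshift	30
c12_pt	KRAS	p.G12A	missense	99.74
c12_hep_s1	KRAS	p.G12A	missense	56.72
c12_pul_m1	KRAS	p.G12A	missense	34.15
c12_pul_m2	KRAS	p.G12A	missense	19.63
c13_pul_s1	ABL1	p.P315S	missense	30
c13_pul_s2	ABL1	p.P315S	missense	30
c13_pt	APC	p.R876*	nonsense	30
c13_pul_s1	APC	p.R876*	nonsense	30
c13_pt	APC	p.E1284*	nonsense	30
c13_pul_s1	APC	p.E1284*	nonsense	30
c13_pul_s2	APC	p.E1284*	nonsense	30
c13_pul_s1	ERBB4	p.D300N	missense	30
c13_pul_s2	ERBB4	p.D300N	missense	30
c13_pt	KRAS	p.G12D	missense	19.83
c13_hep_s1	KRAS	p.G12V	missense	16.44
c13_pul_s1	KRAS	p.G12V	missense	5.62
c13_pul_s2	KRAS	p.G12V	missense	25.72
c14_pt	APC	p.T1430Pfs*	frameshift	30
c14_hep_s1	APC	p.T1430Pfs*	frameshift	30
c14_hep_s2	APC	p.T1430Pfs*	frameshift	30
c14_pul_s1	APC	p.T1430Pfs*	frameshift	30
c14_pt	NRAS	p.Q61R	missense	44.31
c14_hep_s1	NRAS	p.Q61R	missense	66.91
c14_hep_s2	NRAS	p.Q61R	missense	44.74
c14_pul_s1	NRAS	p.Q61R	missense	46.17
c14_pt	TP53	p.R175H	missense	30
c14_hep_s1	TP53	p.R175H	missense	30
c14_hep_s2	TP53	p.R175H	missense	30
c14_pul_s1	TP53	p.R175H	missense	30
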