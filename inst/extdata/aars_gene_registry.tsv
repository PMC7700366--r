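# aaRS / AIMP / reference gene panel (43 genes).
# locality: cytoplasmic | mitochondrial | dual. GARS1 and KARS1 serve both
# compartments and are listed as dual; locality of AIMP and reference genes
# is a cytoplasmic placeholder (panel locality counts apply to family=aaRS
# only). EPRS1 is the bifunctional glutamyl-prolyl synthetase (one gene, two
# catalytic activities); FARSA/FARSB are the two chains of PheRS (two genes,
# one enzyme), so 20 cytoplasmic enzymes map to 20 gene symbols with dual
# genes counted. msc_member marks multi-synthetase-complex components
# (eight aaRS genes -- EPRS1 contributes two of the complex's nine synthetase
# activities -- plus the three AIMPs).
# EEF1E1 is AIMP3 under its HGNC symbol.
symbol	locality	family	msc_member
AARS1	cytoplasmic	aaRS	FALSE
CARS1	cytoplasmic	aaRS	FALSE
DARS1	cytoplasmic	aaRS	TRUE
EPRS1	cytoplasmic	aaRS	TRUE
FARSA	cytoplasmic	aaRS	FALSE
FARSB	cytoplasmic	aaRS	FALSE
GARS1	dual	aaRS	FALSE
HARS1	cytoplasmic	aaRS	FALSE
IARS1	cytoplasmic	aaRS	TRUE
KARS1	dual	aaRS	TRUE
LARS1	cytoplasmic	aaRS	TRUE
MARS1	cytoplasmic	aaRS	TRUE
NARS1	cytoplasmic	aaRS	FALSE
QARS1	cytoplasmic	aaRS	TRUE
RARS1	cytoplasmic	aaRS	TRUE
SARS1	cytoplasmic	aaRS	FALSE
TARS1	cytoplasmic	aaRS	FALSE
VARS1	cytoplasmic	aaRS	FALSE
WARS1	cytoplasmic	aaRS	FALSE
YARS1	cytoplasmic	aaRS	FALSE
AARS2	mitochondrial	aaRS	FALSE
CARS2	mitochondrial	aaRS	FALSE
DARS2	mitochondrial	aaRS	FALSE
EARS2	mitochondrial	aaRS	FALSE
FARS2	mitochondrial	aaRS	FALSE
HARS2	mitochondrial	aaRS	FALSE
IARS2	mitochondrial	aaRS	FALSE
LARS2	mitochondrial	aaRS	FALSE
MARS2	mitochondrial	aaRS	FALSE
NARS2	mitochondrial	aaRS	FALSE
PARS2	mitochondrial	aaRS	FALSE
RARS2	mitochondrial	aaRS	FALSE
SARS2	mitochondrial	aaRS	FALSE
TARS2	mitochondrial	aaRS	FALSE
VARS2	mitochondrial	aaRS	FALSE
WARS2	mitochondrial	aaRS	FALSE
YARS2	mitochondrial	aaRS	FALSE
AIMP1	cytoplasmic	AIMP	TRUE
AIMP2	cytoplasmic	AIMP	TRUE
EEF1E1	cytoplasmic	AIMP	TRUE
RB1	cytoplasmic	reference	FALSE
MYC	cytoplasmic	reference	FALSE
EIF4E	cytoplasmic	reference	FALSE
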