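# Hand-curated subset of substructure classes commonly flagged by published
# PAINS (pan-assay interference) filters: quinones, rhodanines, catechols,
# azo and hydrazone dyes, Michael acceptors, and related motifs. This is a
# small demonstration/test list, NOT the full 480-pattern pattern-checker
# set; published PAINS translations differ, so supply your own list for
# production triage.
# Layout: name<TAB>SMARTS
rhodanine_core	O=C1CSC(=S)N1
thiazolidinone_imine	O=C1CSC(=N)N1
quinone_para	O=C1C=CC(=O)C=C1
quinone_ortho	O=C1C(=O)C=CC=C1
catechol	c1ccc(O)c(O)c1
hydroquinone	Oc1ccc(O)cc1
azo_aromatic	cN=Nc
hydrazone_aryl	c[CH]=N[NH]
ene_one_michael	C=CC(=O)[#6]
isothiazolone	O=C1C=CSN1
mannich_phenol	Oc1ccccc1CN
alkylidene_barbiturate	O=C1NC(=O)NC(=O)C1=C
nitro_aromatic	c[N+](=O)[O-]
thiourea	NC(=S)N
styryl_ketone	C(=O)C=Cc1ccccc1
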