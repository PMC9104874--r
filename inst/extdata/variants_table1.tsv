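variant_id	gene	genomic_change	protein_change	consequence	maf_reference	clinvar_class	acmg_class	GERP	PhyloP	PhastCons	REVEL	MetaLR	MetaSVM	CONDEL	PROVEAN	CADD_phred	dbscSNV_ADA	dbscSNV_RF	MaxEntScan_class	HSF_class
RAD51C:c.414G>C	RAD51C	g.56774063G>C	p.Leu138Phe	missense	1e-05	pathogenic	likely_pathogenic	conserved	conserved	conserved	pathogenic	tolerated	tolerated	damaging	damaging	damaging	NA	NA	NA	NA
RAD51C:c.705G>T	RAD51C	g.56780690G>T	p.Lys235Asn	missense	1e-05	conflicting	pathogenic	conserved	conserved	conserved	benign	tolerated	tolerated	tolerated	tolerated	damaging	affecting_splicing	affecting_splicing	affecting_splicing	affecting_splicing
RAD51D:c.137C>G	RAD51D	g.33446137G>C	p.Ser46Cys	missense	1e-04	conflicting	vus	conserved	conserved	conserved	pathogenic	tolerated	tolerated	damaging	damaging	damaging	NA	NA	NA	NA
RAD51D:c.620C>T	RAD51D	g.33430520G>A	p.Ser207Leu	missense	1e-04	conflicting	vus	conserved	conserved	conserved	pathogenic	damaging	damaging	damaging	damaging	damaging	NA	NA	NA	NA
RAD51D:c.694C>T	RAD51D	g.33430317G>A	p.Arg232Ter	nonsense	3e-05	pathogenic	pathogenic	conserved	conserved	conserved	NA	NA	NA	NA	NA	damaging	NA	NA	NA	NA
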