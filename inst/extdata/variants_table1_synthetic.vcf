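##fileformat=VCFv4.2
##reference=GRCh37
##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">
##INFO=<ID=HGVSC,Number=1,Type=String,Description="HGVS coding change">
##INFO=<ID=PCHANGE,Number=1,Type=String,Description="Protein change">
##INFO=<ID=CSQCLASS,Number=1,Type=String,Description="Consequence class">
##INFO=<ID=MAF_REF,Number=1,Type=Float,Description="Reference population allele frequency">
##INFO=<ID=CLINVAR,Number=1,Type=String,Description="ClinVar classification">
##INFO=<ID=ACMG,Number=1,Type=String,Description="ACMG classification">
##INFO=<ID=GERP,Number=1,Type=String,Description="GERP++ score or label">
##INFO=<ID=PhyloP,Number=1,Type=String,Description="PhyloP score or label">
##INFO=<ID=PhastCons,Number=1,Type=String,Description="PhastCons score or label">
##INFO=<ID=REVEL,Number=1,Type=String,Description="REVEL score or label">
##INFO=<ID=MetaLR,Number=1,Type=String,Description="MetaLR score or label">
##INFO=<ID=MetaSVM,Number=1,Type=String,Description="MetaSVM score or label">
##INFO=<ID=CONDEL,Number=1,Type=String,Description="CONDEL score or label">
##INFO=<ID=PROVEAN,Number=1,Type=String,Description="PROVEAN score or label">
##INFO=<ID=CADD_phred,Number=1,Type=String,Description="CADD Phred score or label">
##INFO=<ID=dbscSNV_ADA,Number=1,Type=String,Description="dbscSNV AdaBoost score or label">
##INFO=<ID=dbscSNV_RF,Number=1,Type=String,Description="dbscSNV random-forest score or label">
##INFO=<ID=MaxEntScan_class,Number=1,Type=String,Description="MaxEntScan splice classification">
##INFO=<ID=HSF_class,Number=1,Type=String,Description="Human Splicing Finder classification">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO
17	56774063	rv1	G	C	.	PASS	GENE=RAD51C;HGVSC=c.414G>C;PCHANGE=p.Leu138Phe;CSQCLASS=missense;MAF_REF=0.00001;CLINVAR=pathogenic;ACMG=likely_pathogenic;GERP=conserved;PhyloP=conserved;PhastCons=conserved;REVEL=pathogenic;MetaLR=tolerated;MetaSVM=tolerated;CONDEL=damaging;PROVEAN=damaging;CADD_phred=damaging
17	56780690	rv2	G	T	.	PASS	GENE=RAD51C;HGVSC=c.705G>T;PCHANGE=p.Lys235Asn;CSQCLASS=missense;MAF_REF=0.00001;CLINVAR=conflicting;ACMG=pathogenic;GERP=conserved;PhyloP=conserved;PhastCons=conserved;REVEL=benign;MetaLR=tolerated;MetaSVM=tolerated;CONDEL=tolerated;PROVEAN=tolerated;CADD_phred=damaging;dbscSNV_ADA=affecting_splicing;dbscSNV_RF=affecting_splicing;MaxEntScan_class=affecting_splicing;HSF_class=affecting_splicing
17	33446137	rv3	G	C	.	PASS	GENE=RAD51D;HGVSC=c.137C>G;PCHANGE=p.Ser46Cys;CSQCLASS=missense;MAF_REF=0.0001;CLINVAR=conflicting;ACMG=vus;GERP=conserved;PhyloP=conserved;PhastCons=conserved;REVEL=pathogenic;MetaLR=tolerated;MetaSVM=tolerated;CONDEL=damaging;PROVEAN=damaging;CADD_phred=damaging
17	33430520	rv4	G	A	.	PASS	GENE=RAD51D;HGVSC=c.620C>T;PCHANGE=p.Ser207Leu;CSQCLASS=missense;MAF_REF=0.0001;CLINVAR=conflicting;ACMG=vus;GERP=conserved;PhyloP=conserved;PhastCons=conserved;REVEL=pathogenic;MetaLR=damaging;MetaSVM=damaging;CONDEL=damaging;PROVEAN=damaging;CADD_phred=damaging
17	33430317	rv5	G	A	.	PASS	GENE=RAD51D;HGVSC=c.694C>T;PCHANGE=p.Arg232Ter;CSQCLASS=nonsense;MAF_REF=0.00003;CLINVAR=pathogenic;ACMG=pathogenic;GERP=conserved;PhyloP=conserved;PhastCons=conserved;CADD_phred=damaging
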