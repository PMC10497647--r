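# oncodda knowledgebase
[meta]
version
tiny-1
[tumor_types]
melanoma
lung
CRC
[genes]
symbol	aliases
BRAF	B-RAF
KRAS	
EGFR	ERBB1
MET	
TP53	
[compounds]
id	name	registered	approved_indications
CPD_VEMU	vemurafenib-like	TRUE	melanoma
CPD_TRAM	trametinib-like	TRUE	
CPD_DEV	dev-compound	FALSE	
[evidence]
id	subject_gene	subject_alteration	object_kind	object_id	direction	evidence_class	tumor_type	base_reliability	source_ref
E01	BRAF	p.V600E	oncogenicity		+1	clinical			ref:E01
E02	BRAF	p.V600E	oncogenicity		+1	clinical	melanoma	8	ref:E02
E03	BRAF		oncogenicity		+1	preclinical			ref:E03
E04	BRAF	p.V600E	compound	CPD_VEMU	+1	clinical	melanoma		ref:E04
E05	BRAF		compound	CPD_DEV	+1	preclinical			ref:E05
E06	BRAF		target	MET	+1	preclinical			ref:E06
E07	MET		compound	CPD_TRAM	+1	preclinical			ref:E07
E08	KRAS		oncogenicity		+1	clinical			ref:E08
E09	KRAS		compound	CPD_VEMU	-1	clinical			ref:E09
E10	EGFR	p.L858R	oncogenicity		+1	clinical	lung	6	ref:E10
E11	EGFR	p.L858R	oncogenicity		+1	clinical		6	ref:E11
E12	EGFR		oncogenicity		+1	preclinical			ref:E12
E13	EGFR		compound	CPD_TRAM	+1	in_silico			ref:E13
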