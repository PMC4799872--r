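patient_id	sex	age	phenotype	genes	region	direction	classification	span_kind	panel
51	male	36 years	DCM	LMNA	Exon 1	loss	Likely pathogenic	intragenic	PanCardio
450	male	49 years	DCM	TTN	Exon 193-244	gain	VUS	intragenic	DCM
1060	female	39 years	DCM	LAMP2	Exon 8-9	loss	Pathogenic	intragenic	PanCardio
104	male	55 years	HCM	MYOZ2	Exon 2	gain	VUS	intragenic	HCM
267	female	44 years	HCM	MYBPC3	Exon 12-20	loss	Pathogenic	intragenic	HCM
958	male	57 years	HCM	NEXN	Whole gene	gain	VUS	whole_gene	PanCardio
1044	female	1 month	HCM	GLA/LAMP2/EMD/TAZ	X chr	gain	VUS	multi_gene	PanCardio
322	male	1 year	LVNC	PKP2	Whole gene	gain	VUS	whole_gene	PanCardio
1233	male	15 years	ARVC	PKP2	Exon 8	loss	Likely pathogenic	intragenic	PanCardio
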