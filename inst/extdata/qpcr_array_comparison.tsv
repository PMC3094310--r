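condition	gene_id	description	qpcr_value	qpcr_significant	M	B
Ni	AJ625847	metallothionein isoform mt-10b	2.8	TRUE	1.46	11.5
Ni	AY566247	metallothionein isoform mt-20-IV	0.6	FALSE	NA	NA
Ni	AJ624405	gm2 ganglioside activator protein	13.6	TRUE	2.63	7.0
Ni	AJ624495	gm2 ganglioside activator protein	-4.4	TRUE	-0.87	9.7
Ni	AJ625863	apolipophorin precursor	0.8	TRUE	0.56	5.1
Ni	AJ625569	chitinase	1.7	FALSE	-0.08	-7.2
Ni	AJ624093	chitinase	1.5	FALSE	-0.41	2.3
Ni	AJ624637	chitinase	0.9	FALSE	-0.52	3.6
Ni	AJ625051	chitinase 1	0.4	FALSE	-0.8	7.5
Ni	AJ623463	beta-n-acetyl-hexosaminidase	-0.1	FALSE	0.03	-7.5
Ni	AJ625116	actin	-0.0	FALSE	-0.05	-6.9
Ni	AJ625243	p-53 like	0.1	FALSE	-0.11	-7.2
CHP	AJ625847	metallothionein isoform mt-10b	-0.3	FALSE	-0.1	-6.3
CHP	AY566247	metallothionein isoform mt-20-IV	-0.1	FALSE	NA	NA
CHP	AJ624405	gm2 ganglioside activator protein	-0.7	FALSE	-0.3	-5.4
CHP	AJ624495	gm2 ganglioside activator protein	5.6	TRUE	-0.6	-5.0
CHP	AJ625863	apolipophorin precursor	0.3	FALSE	-0.1	-6.1
CHP	AJ625569	chitinase	6.4	TRUE	1.9	12.2
CHP	AJ624093	chitinase	5.4	TRUE	1.9	9.9
CHP	AJ624637	chitinase	5.7	TRUE	1.6	4.5
CHP	AJ625051	chitinase 1	5.1	TRUE	3.2	11.5
CHP	AJ623463	beta-n-acetyl-hexosaminidase	-0.4	FALSE	-0.3	-6.1
CHP	AJ625116	actin	0.4	FALSE	0.1	-6.3
CHP	AJ625243	p-53 like	-0.4	FALSE	0.3	-6.3
Mix	AJ625847	metallothionein isoform mt-10b	1.8	TRUE	0.9	4.4
Mix	AY566247	metallothionein isoform mt-20-IV	0.0	FALSE	NA	NA
Mix	AJ624405	gm2 ganglioside activator protein	-7.6	TRUE	0.5	-1.3
Mix	AJ624495	gm2 ganglioside activator protein	6.7	TRUE	0.4	0.1
Mix	AJ625863	apolipophorin precursor	-0.6	FALSE	-0.0	-6.4
Mix	AJ625569	chitinase	6.6	TRUE	1.7	4.7
Mix	AJ624093	chitinase	5.6	TRUE	2.0	0.4
Mix	AJ624637	chitinase	6.0	TRUE	1.7	1.8
Mix	AJ625051	chitinase 1	6.2	TRUE	2.0	0.3
Mix	AJ623463	beta-n-acetyl-hexosaminidase	2.9	TRUE	1.1	-5.7
Mix	AJ625116	actin	0.6	TRUE	0.5	2.7
Mix	AJ625243	p-53 like	-0.1	FALSE	-0.6	-3.9
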