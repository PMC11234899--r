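hypothesis_id	label	member_type	member_id	expected_direction
h_amino_acid_transport	Amino acid transport and metabolism	category	E	oligotroph_enriched
h_motility	Chemotaxis and motility	category	N	copiotroph_enriched
h_lipid_transport	Lipid transport and metabolism	category	I	oligotroph_enriched
h_secondary_metabolites	Secondary metabolite biosynthesis, transport and metabolism	category	Q	oligotroph_enriched
h_defense	Defense mechanisms	category	V	copiotroph_enriched
h_transcription	Transcription	category	K	copiotroph_enriched
h_signal_transduction	Signal transduction	category	T	copiotroph_enriched
h_replication_repair	Replication, recombination and repair	category	L	copiotroph_enriched
h_prox	Glycine betaine ABC transporter (ProX)	cog	COG2113	oligotroph_enriched
h_rpoe	RNA polymerase sigma factor, extracytoplasmic E (rpoE)	cog	COG1595	oligotroph_enriched
h_trehalose	Trehalose synthase and transporter	cog	COG0380	oligotroph_enriched
h_trehalose	Trehalose synthase and transporter	cog	COG1653	oligotroph_enriched
h_coxl	Form I CO dehydrogenase large subunit (coxL)	cog	COG1529	oligotroph_enriched
h_nife_hydrogenase	[NiFe] hydrogenase	cog	COG0374	oligotroph_enriched
h_thiamine	Thiamine biosynthesis	cog	COG0422	copiotroph_enriched
h_phb_pha	Poly-beta-hydroxybutyrate / polyhydroxyalkanoate synthesis	cog	COG3243	oligotroph_enriched
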