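species	family	phenotype	wgd_events	n_type1_active	n_type1_inactive	n_type1_lowexpr	s_rnase_status	literature_route_label	status	provisional
Solanum habrochaites	Solanaceae	TYPE1_SI	1	1	0	0	intact	R1+b	reported	FALSE
Citrus maxima	Rutaceae	TYPE1_SI	1	1	0	0	intact	R1+b	reported	FALSE
Olea europaea	Oleaceae	TYPE1_SI	1	1	0	0	intact	R1+b	reported	FALSE
Ziziphus jujube	Rhamnaceae	TYPE1_SI	1	1	0	0	intact	R1+b	reported	FALSE
Ricinus communis	Euphorbiaceae	TYPE1_SI	1	1	0	0	intact	R1+b	reported	FALSE
Antirrhinum hispanicum	Plantaginaceae	TYPE1_SI	1	1	1	1	intact	R1+a	reported	FALSE
Prunus mume	Rosaceae	TYPE1_SI	1	1	1	1	intact	R1+a	reported	TRUE
Citrus clementina	Rutaceae	TYPE1_SI	1	1	1	1	intact	R1+a	reported	TRUE
Antirrhinum majus	Plantaginaceae	SC	1	0	1	0	deleted	R2	reported	FALSE
Solanum lycopersicum	Solanaceae	SC	1	0	1	0	pseudogene	R2	reported	FALSE
Gossypium raimondii	Malvaceae	SC	1	2	0	0	intact	R2	reported	FALSE
Phaseolus vulgaris	Fabaceae	SC	1	2	0	0	intact	R2	reported	FALSE
Aquilegia coerulea	Ranunculaceae	SC	1	4	0	0	intact	R2	reported	FALSE
Brassica oleracea	Brassicaceae	TYPE2_SI	1	0	0	0	NA	R3+d	reported	FALSE
Primula veris	Primulaceae	TYPE4_SI	0	0	0	0	NA	R3+d	reported	FALSE
Helianthus annuus	Asteraceae	SSI_OTHER	1	0	0	0	NA	R3+d	reported	FALSE
Papaver somniferum	Papaveraceae	TYPE3_SI	1	0	4	0	NA	R1+d	reported	FALSE
Coffea canephora	Rubiaceae	GSI_OTHER	0	2	0	0	intact	ambiguous_a_d	reported	FALSE
Arabidopsis thaliana	Brassicaceae	SC	1	0	0	0	NA	R2_type2_system	reported	FALSE
Petunia inflata	Solanaceae	TYPE1_SI	1	1	0	0	intact	NA	inferred	FALSE
Prunus avium	Rosaceae	TYPE1_SI	1	1	0	0	intact	NA	inferred	FALSE
Malus domestica	Rosaceae	TYPE1_SI	1	1	0	0	intact	NA	inferred	FALSE
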