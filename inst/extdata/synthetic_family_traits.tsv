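taxon	state
Ginkgoaceae	CLASSI_II_UNLINKED
Poaceae	CLASSI_II_UNLINKED
Bromeliaceae	CLASSI_II_LINKED
Papaveraceae	TYPE1_PLUS_TYPE3
Ranunculaceae	TYPE1_LINKED
Primulaceae	TYPE4_SLOCUS
Asteraceae	ABSENT
Rubiaceae	TYPE1_LINKED
Solanaceae	TYPE1_LINKED
Plantaginaceae	TYPE1_LINKED
Oleaceae	TYPE1_LINKED
Rosaceae	TYPE1_LINKED
Rhamnaceae	TYPE1_LINKED
Fabaceae	TYPE1_LINKED
Brassicaceae	TYPE2_SLOCUS
Malvaceae	TYPE1_LINKED
Rutaceae	TYPE1_LINKED
Euphorbiaceae	TYPE1_LINKED
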