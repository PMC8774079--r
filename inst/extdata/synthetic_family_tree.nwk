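(Ginkgoaceae:300,((Poaceae:60,Bromeliaceae:60):90,((Papaveraceae:40,Ranunculaceae:40):80,((Primulaceae:100,(Asteraceae:90,(Rubiaceae:85,(Solanaceae:65,(Plantaginaceae:50,Oleaceae:50):15):20):5):10):15,(((Rosaceae:75,Rhamnaceae:75):15,Fabaceae:90):10,((Brassicaceae:70,Malvaceae:70):15,(Rutaceae:75,Euphorbiaceae:75):10):15):15):5):30):150);
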