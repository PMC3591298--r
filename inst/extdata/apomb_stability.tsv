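species	dg_apo	c_mb	class	flag
Pig	-4.4	NA	terrestrial	
Horse	-4.8	NA	terrestrial	
Sheep	-4.9	NA	terrestrial	
Human	-5.7	NA	terrestrial	
Bovine	-5.8	NA	terrestrial	
Dog	-6.3	NA	terrestrial	
Dwarf_sperm_whale	-5.1	NA	cetacean	
Pygmy_sperm_whale	-7.4	NA	cetacean	
Sperm_whale	-7.5	NA	cetacean	
Goose_beaked_whale	-7.8	NA	cetacean	
Dolphin	-8.4	NA	cetacean	
Minke_whale	-8.7	0.37	cetacean	listed as -8.4 in the concluding comparison
Harbor_porpoise	-7.8	0.40	cetacean	stability printed only in the concluding comparison
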