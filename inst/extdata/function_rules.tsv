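pattern	group
phylum:Desulfobacterota	sulfate_respiration
phylum:Desulfobacterota	iron_respiration
genus:Desulfovibrio	sulfate_respiration
phylum:Cyanobacteria	phototrophy
phylum:Cyanobacteria	nitrogen_fixation
genus:Nostoc	nitrogen_fixation
phylum:Halanaerobiaeota	cellulolysis
phylum:Euryarchaeota	dark_hydrogen_oxidation
phylum:Halobacterota	dark_hydrogen_oxidation
genus:Methanobacterium	methanogenesis
genus:Methanosarcina	methanogenesis
phylum:Firmicutes	fermentation
genus:Clostridium	cellulolysis
genus:Bacillus	fermentation
phylum:Crenarchaeota	nitrification
genus:Nitrososphaera	nitrification
genus:Bradyrhizobium	nitrogen_fixation
genus:Streptomyces	cellulolysis
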