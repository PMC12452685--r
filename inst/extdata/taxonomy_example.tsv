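organism	rank	lineage
Ochrobactrum sp. G-1	genus	Bacteria;Pseudomonadota;a-proteobacteria;Hyphomicrobiales;Brucellaceae;Ochrobactrum
Rhizobium leguminosarum	species	Bacteria;Pseudomonadota;a-proteobacteria;Hyphomicrobiales;Rhizobiaceae;Rhizobium;Rhizobium leguminosarum
Variovorax paradoxus	species	Bacteria;Pseudomonadota;b-proteobacteria;Burkholderiales;Comamonadaceae;Variovorax;Variovorax paradoxus
Variovorax boronicumulans	species	Bacteria;Pseudomonadota;b-proteobacteria;Burkholderiales;Comamonadaceae;Variovorax;Variovorax boronicumulans
Agrobacterium tumefaciens	species	Bacteria;Pseudomonadota;a-proteobacteria;Hyphomicrobiales;Rhizobiaceae;Agrobacterium;Agrobacterium tumefaciens
Pseudomonas sp.	genus	Bacteria;Pseudomonadota;g-proteobacteria;Pseudomonadales;Pseudomonadaceae;Pseudomonas
Rhodospirillales bacterium	order	Bacteria;Pseudomonadota;a-proteobacteria;Rhodospirillales
Pseudomonadota bacterium	phylum	Bacteria;Pseudomonadota
bacterium	domain	Bacteria
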