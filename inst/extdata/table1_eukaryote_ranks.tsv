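kingdom	phylum	class	order	family	genus	species
Animalia	Annelida	2	7	17	16
Animalia	Arthropoda	3	12	35	38	8
Animalia	Brachiopoda	1
Animalia	Bryozoa	1	13
Animalia	Chaetognatha	1	1	1
Animalia	Chordata	5	17	45	73	36
Animalia	Cnidaria	2	5	9	7
Animalia	Ctenophore	1	1	1	1
Animalia	Echinodermata	3	23	4	2
Animalia	Gastrotricha	1	1
Animalia	Mollusca	4	15	22	19	5
Animalia	Nematoda	1	1	1
Animalia	Nemertea	2	1	2	2
Animalia	Platyhelminthes	4	3	2
Animalia	Porifera	3	6	6	6
Animalia	Xenacoelomorpha	1	1
Chromista	Bigyra	1	2	2	3
Chromista	Cercozoa	4	4	3	4
Chromista	Ciliophora	7	15	24
Chromista	Cryptophyta	3	3	6	6
Chromista	Haptophyta	4	5	5	4	1
Chromista	Heliozoa	1	1	1	1
Chromista	Myzozoa	3	10	25	36	2
Chromista	Ochrophyta	9	3	12	7
Chromista	Oomycota	1	3	2
Chromista	Radiozoa	2	2	1	1
Fungi	Ascomycota	3	4	3
Fungi	Basidiomycota	2	2	1	1
Fungi	Chytridiomycota	1	1	1	1
Fungi	Entomophthoromycota	1	1	11
Plantae	Chlorophyta	7	10	11	17
Plantae	Glaucophyta	1	1	1
Plantae	Rhodophyta	1	5	7	3
Plantae	Streptophyta	1	1	1	11	2
Protozoa	Amoebozoa	1	1	1
Protozoa	Apusozoa	2	3
Protozoa	Choanozoa	2	1	23
Protozoa	Picozoa	1	1	1
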