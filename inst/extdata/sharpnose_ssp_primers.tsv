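name	sequence	orientation	role	target_taxon	expected_product_bp
Racut-555	TTAACGTTCTGTGCGTGTCGAGT	forward	species_specific	R. acutus	230
Rpor-1260	GCGAGGCACACCTCGGCAC	forward	species_specific	R. porosus	420
Rlong-1116	GACTTGCTCTGTCCTTGAGCCC	forward	species_specific	R. longurio	560
Rter-946	TGTGAATAGGGGCAGCCGACA	forward	species_specific	R. terranovae	720
Rolig-741	TACCGGGAGAGCTCGGAAAACGT	forward	species_specific	R. oligolinx	850
Rtay-482	AACGGTTCGGGTGCTCCGGCA	forward	species_specific	R. taylori	1150
Rlal-293	GGCACGTAGGCACCGCCCGCTAT	forward	species_specific	R. lalandei	1300
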