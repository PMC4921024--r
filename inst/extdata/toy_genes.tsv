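gene_id	genome_id	length	roles	subsystems
g1	genomeA	700	Phosphoribosyl-ATP pyrophosphatase;Phosphoribosyl-AMP cyclohydrolase	Histidine biosynthesis
g2	genomeA	650	uncharacterized multi-motif protein	
g3	genomeA	500	signal transduction module;ligand recognition module	Two-component systems
g4	genomeB	190	Phosphoribosyl-ATP pyrophosphatase	Histidine biosynthesis
g5	genomeB	310	Phosphoribosyl-AMP cyclohydrolase	Histidine biosynthesis
g6	genomeB	145	signal transduction module	Two-component systems
g7	genomeB	155	ligand recognition module	Two-component systems
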