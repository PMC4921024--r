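role	reaction_id	metabolite	side
Phosphoribosyl-ATP pyrophosphatase	rxn00100	Phosphoribosyl-ATP	substrate
Phosphoribosyl-ATP pyrophosphatase	rxn00100	Phosphoribosyl-AMP	product
Phosphoribosyl-AMP cyclohydrolase	rxn00101	Phosphoribosyl-AMP	substrate
Phosphoribosyl-AMP cyclohydrolase	rxn00101	Phosphoribosylformimino-AICAR-phosphate	product
Cyclohexadienyl dehydratase	rxn00200	Prephenate	substrate
Cyclohexadienyl dehydratase	rxn00200	Phenylpyruvate	product
Periplasmic chorismate mutase I precursor	rxn00201	Chorismate	substrate
Periplasmic chorismate mutase I precursor	rxn00201	Prephenate	product
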