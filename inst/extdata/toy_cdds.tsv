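cdd_id	model_length	description
cddA	185	phosphoribosyl-ATP pyrophosphohydrolase domain
cddB	300	phosphoribosyl-AMP cyclohydrolase domain
cddC	140	receiver module
cddD	150	ligand-binding module
cddX	70	small helical sub-domain
cddY	80	small beta-barrel sub-domain
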