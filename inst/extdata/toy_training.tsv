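gene_id	status	source
g1	confirmed_fusion	Serres;SEED
g2	uncertain	IMG
g3	rejected	IMG
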