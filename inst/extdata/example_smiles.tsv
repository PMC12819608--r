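# Example SMILES file in the ID<TAB>SMILES dialect (synthetic toy list,
# common small molecules for reader smoke tests only).
ETH	CCO
BNZ	c1ccccc1
ASA	CC(=O)Oc1ccccc1C(=O)O
CAF	Cn1cnc2c1c(=O)n(C)c(=O)n2C
PCM	CC(=O)Nc1ccc(O)cc1
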