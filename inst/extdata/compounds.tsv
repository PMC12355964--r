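name	rank	smiles
lactose	1	C(C1C(C(C(C(O1)OC2C(OC(C(C2O)O)O)CO)O)O)O)O
adenosine triphosphate	1	C1=NC(=C2C(=N1)N(C=N2)C3C(C(C(O3)COP(=O)(O)OP(=O)(O)OP(=O)(O)O)O)O)N
p-nitrophenyl phosphate	1	C1=CC(=CC=C1[N+](=O)[O-])OP(=O)(O)O
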