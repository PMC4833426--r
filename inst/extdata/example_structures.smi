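# demonstration structures, one SMILES per line with trailing compound id
CC1SC(=S)NC1=O CMP1
c1ccccc1O CMP2
CCO CMP3
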