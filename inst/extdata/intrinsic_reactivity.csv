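residue_type,ir
K,2.2
D,0.42
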