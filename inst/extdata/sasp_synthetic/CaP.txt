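node: CaP
arity: 2
role: pump
regulators: Ca
0 0
1 1
2 1
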