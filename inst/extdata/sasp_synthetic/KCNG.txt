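node: KCNG
arity: 2
role: channel
regulators: cGMP KCNG V
0 0 0 0
0 0 1 0
0 0 2 0
0 1 0 0
0 1 1 0
0 1 2 0
1 0 0 0
1 0 1 1
1 0 2 1
1 1 0 0
1 1 1 0
1 1 2 0
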