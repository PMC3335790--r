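receptor = S1P1
helix1.50 = 63
helix2.50 = 91
helix3.50 = 142
helix4.50 = 169
helix5.50 = 221
helix6.50 = 276
helix7.50 = 308
note = human S1P1; verify anchors against the structure
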