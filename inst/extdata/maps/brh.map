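receptor = brh
helix1.50 = 55
helix2.50 = 83
helix3.50 = 135
helix4.50 = 161
helix5.50 = 215
helix6.50 = 267
helix7.50 = 303
note = bovine rhodopsin; anchors cross-checked: 3.28=Glu113, 7.43=Lys296, 6.30=Glu247
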