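receptor = CXCR4
helix1.50 = 56
helix2.50 = 84
helix3.50 = 134
helix4.50 = 161
helix5.50 = 211
helix6.50 = 254
helix7.50 = 299
note = human CXCR4; BW/structure alignment mismatches reported at helix II for this receptor - verify before use
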