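receptor = A2A
helix1.50 = 24
helix2.50 = 52
helix3.50 = 102
helix4.50 = 129
helix5.50 = 189
helix6.50 = 248
helix7.50 = 285
note = human A2A adenosine; 6.48=Trp246 consistent with 6.50=Pro248
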