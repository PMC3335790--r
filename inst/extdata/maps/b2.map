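receptor = b2
helix1.50 = 51
helix2.50 = 79
helix3.50 = 131
helix4.50 = 158
helix5.50 = 211
helix6.50 = 288
helix7.50 = 323
note = human beta2 adrenergic; 6.30=Glu268 consistent with 6.50=Pro288
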