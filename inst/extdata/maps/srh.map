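receptor = srh
helix1.50 = 51
helix2.50 = 78
helix3.50 = 132
helix4.50 = 158
helix5.50 = 212
helix6.50 = 269
helix7.50 = 312
note = squid rhodopsin; 7.50 anchored by retinal Lys305 at 7.43; verify remaining anchors against the structure
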