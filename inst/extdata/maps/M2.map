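receptor = M2
helix1.50 = 41
helix2.50 = 69
helix3.50 = 121
helix4.50 = 148
helix5.50 = 198
helix6.50 = 402
helix7.50 = 423
note = human muscarinic M2; 3.50 anchored by 3.32=Asp103; verify remaining anchors against the structure
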