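receptor = D3
helix1.50 = 52
helix2.50 = 80
helix3.50 = 128
helix4.50 = 152
helix5.50 = 205
helix6.50 = 344
helix7.50 = 370
note = human dopamine D3; 3.50 anchored by 3.32=Asp110; verify remaining anchors against the structure
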