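receptor = H1
helix1.50 = 44
helix2.50 = 73
helix3.50 = 125
helix4.50 = 152
helix5.50 = 202
helix6.50 = 430
helix7.50 = 455
note = human histamine H1; 3.50 anchored by 3.32=Asp107; verify remaining anchors against the structure
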