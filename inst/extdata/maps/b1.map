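receptor = b1
helix1.50 = 59
helix2.50 = 87
helix3.50 = 139
helix4.50 = 166
helix5.50 = 219
helix6.50 = 305
helix7.50 = 340
note = turkey beta1 adrenergic; verify anchors against the structure
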