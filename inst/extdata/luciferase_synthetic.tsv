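group	activity
control	0.97
control	1.04
control	0.99
control	1.02
control	0.96
control	1.02
repressor	0.62
repressor	0.71
repressor	0.66
repressor	0.74
repressor	0.63
repressor	0.72
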