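direction	total	k4_only	k27_only	both
up	2586	1770	NA	99
down	2659	4	169	0
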