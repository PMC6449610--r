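mark	increased	decreased
H3K4me3	14576	130
H3K27ac	921	1304
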