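N	S	tp	fp
15841	38	38	9
15841	38	30	854
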