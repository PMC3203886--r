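role	profile
victim	T16304C
suspect	T16126C C16292T C16294T A16399G
stain	16126Y 16292Y 16294Y 16304Y 16399R
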