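time_generations	haploid_size
0	20000
1000	5000
3000	1000
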