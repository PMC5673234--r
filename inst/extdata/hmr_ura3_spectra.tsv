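category	wild type	msh2	msh2 exo1	exo1
1-bp deletion	7	25	24	7
base substitution	40	17	18	40
1-bp insertion	1	6	5	0
complex	1	1	2	3
other	1	1	1	0
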