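# threshold=0
gene	codon	score
NFE2L2	18	1.8431
NFE2L2	18	1.3205
NFE2L2	24	1.3959
NFE2L2	24	1.4382
NFE2L2	77	1.3544
NFE2L2	77	1.3579
NFE2L2	79	1.6122
NFE2L2	79	1.4825
KEAP1	278	1.5229
KEAP1	278	1.8285
KEAP1	323	1.5535
KEAP1	323	1.9075
KEAP1	480	1.8422
KEAP1	480	1.5486
KEAP1	511	1.7844
KEAP1	511	1.5702
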