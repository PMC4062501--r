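figure	ct	fw	lw	verb_predicate	role	path_printed	path
a	NP	T3	T3	induce	ARG0	NP > S < VP < VBD	NP > S < VP < VBD
a	ADVP	efficiently	efficiently	induce	ARGM-MNR	ADVP > S < VP < VBD	ADVP > S < VP < VBD
a	NP	erythroid	differentiation	induce	ARG1	VBD > VP < NP	VBD > VP < NP
a	PP	in	cell	induce	ARGM-LOC	VBD > VP > S < PP	VBD > VP > S < PP
a	RB	thus	thus	induce	ARGM-DIS	VBD > VP < RB	VBD > VP < RB
a	S	overcoming	arrest	induce	ARGM-ADV	VBD > VP < S	VBD > VP < S
b	PP	in	contrast	express	ARGM-DIS	PP > S < VP < VP < VBN	PP > S < VP < VP < VBN
b	NP	mRNA	591/egr2	express	ARG1	NP > S < VP < VBN	NP > S < VP < VP < VBN
b	RB	not	not	express	ARGM-NEG	RB > VP < VBD	RB > VP < VBN
b	PP	in	cell	express	ARGM-LOC	VBD > VP < S < PP	VBN > VP < PP
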