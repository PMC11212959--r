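FORM	UPOS	DEPREL	FEATS	VALENCE
the	DET	det	Definite=Def	_
a	DET	det	Definite=Ind	_
big	ADJ	amod	Degree=Pos	_
small	ADJ	amod	Degree=Pos	_
red	ADJ	amod	Degree=Pos	_
old	ADJ	amod	Degree=Pos	_
green	ADJ	amod	Degree=Pos	_
happy	ADJ	amod	Degree=Pos	_
cat	NOUN	arg	Number=Sing	_
dog	NOUN	arg	Number=Sing	_
bird	NOUN	arg	Number=Sing	_
horse	NOUN	arg	Number=Sing	_
teacher	NOUN	arg	Number=Sing	_
student	NOUN	arg	Number=Sing	_
river	NOUN	arg	Number=Sing	_
garden	NOUN	arg	Number=Sing	_
house	NOUN	arg	Number=Sing	_
apple	NOUN	arg	Number=Sing	_
engine	NOUN	arg	Number=Sing	_
island	NOUN	arg	Number=Sing	_
saw	VERB	root	Tense=Past	transitive
liked	VERB	root	Tense=Past	transitive
chased	VERB	root	Tense=Past	transitive
found	VERB	root	Tense=Past	transitive
admired	VERB	root	Tense=Past	transitive
slept	VERB	root	Tense=Past	intransitive
smiled	VERB	root	Tense=Past	intransitive
vanished	VERB	root	Tense=Past	intransitive
waited	VERB	root	Tense=Past	intransitive
in	ADP	case	_	_
near	ADP	case	_	_
behind	ADP	case	_	_
above	ADP	case	_	_
quietly	ADV	advmod	_	_
quickly	ADV	advmod	_	_
slowly	ADV	advmod	_	_
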