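code	metabolite_id
A	ala__L_c
C	cys__L_c
D	asp__L_c
E	glu__L_c
F	phe__L_c
G	gly_c
H	his__L_c
I	ile__L_c
K	lys__L_c
L	leu__L_c
M	met__L_c
N	asn__L_c
P	pro__L_c
Q	gln__L_c
R	arg__L_c
S	ser__L_c
T	thr__L_c
V	val__L_c
W	trp__L_c
Y	tyr__L_c
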