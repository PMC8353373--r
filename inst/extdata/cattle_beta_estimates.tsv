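breed	breed_name	beta	se
GIO	Girolando	3.211e-5	2.4640e-2
CRI	CriouloLageano	3.193e-5	2.2346e-2
CAN	Canchim	3.150e-5	2.2845e-2
IND	Indubrasil	2.780e-5	2.8360e-2
GIR	Gir	2.544e-5	2.8594e-2
TAB	Tabapua	2.441e-5	4.2235e-2
SIN	Sindhi	2.375e-5	3.9809e-2
PAN	Pantaneiro	2.344e-5	3.3130e-2
ANG	Angus	2.277e-5	3.4902e-2
BRA	Brahman	2.277e-5	3.8608e-2
MOC	MochoNacional	2.259e-5	3.1316e-2
CCB	CaracuBeef	2.205e-5	3.1080e-2
FRA	CriouloLageanoRS	2.153e-5	3.5613e-2
BWS	BrownSwiss	2.038e-5	3.3468e-2
NEL	Nelore	1.907e-5	5.2770e-2
HOL	Holstein	1.812e-5	4.0766e-2
CCD	CaracuDairy	1.734e-5	4.3804e-2
JER	Jersey	1.401e-5	5.6142e-2
CUR	CurraleiroPeDuro	1.102e-5	6.2879e-2
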