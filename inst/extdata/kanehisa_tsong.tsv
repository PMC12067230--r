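# Average relative probability of beta-sheet (Kanehisa & Tsong 1980, Biopolymers 19:1617-1628; AAindex KANM800102)
aa	value
A	0.81
C	1.17
D	0.71
E	0.53
F	1.20
G	0.88
H	0.92
I	1.48
K	0.77
L	1.24
M	1.05
N	0.62
P	0.61
Q	0.98
R	0.85
S	0.92
T	1.18
V	1.66
W	1.18
Y	1.23
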