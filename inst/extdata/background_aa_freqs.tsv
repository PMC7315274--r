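aa	freq
A	0.07007007
R	0.056056056
N	0.036036036
D	0.047047047
C	0.023023023
Q	0.048048048
E	0.071071071
G	0.066066066
H	0.026026026
I	0.043043043
L	0.1001001
K	0.057057057
M	0.021021021
F	0.037037037
P	0.063063063
S	0.083083083
T	0.053053053
W	0.012012012
Y	0.027027027
V	0.06006006
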