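# Synthetic transmembrane-region substitution matrix (non-symmetric stand-in; see package docs)
   A  R  N  D  C  Q  E  G  H  I  L  K  M  F  P  S  T  W  Y  V
A  6 -2 -3 -3  2 -2 -2 -1 -3  1  1 -2  1  0 -2  0 -1 -4 -3  2
R -2  5  0 -2 -4  1  0 -2  0 -4 -3  2 -2 -4 -2 -1 -1 -3 -2 -4
N -3  0  6  1 -4  0  0  0  1 -4 -4  0 -3 -4 -2  1  0 -4 -2 -4
D -3 -2  1  6 -4  0  2 -1 -1 -4 -5 -1 -4 -4 -1  0 -1 -4 -3 -4
C  2 -4 -4 -4 11 -4 -5 -4 -4  1  1 -4  1  0 -4 -2 -2 -3 -3  1
Q -2  1  0  0 -4  5  2 -2  0 -4 -3  1 -1 -4 -1  0 -1 -2 -1 -3
E -2  0  0  2 -5  2  5 -2  0 -4 -4  1 -3 -4 -1  0 -1 -3 -2 -3
G -1 -2  0 -1 -4 -2 -2  6 -2 -5 -5 -2 -4 -4 -2  0 -2 -2 -3 -4
H -3  0  1 -1 -4  0  0 -2  8 -4 -4 -1 -3 -2 -2 -1 -2 -2  2 -4
I  2 -3 -3 -3  2 -3 -3 -4 -3  7  5 -3  4  3 -3 -2 -1 -3 -1  6
L  2 -2 -3 -4  2 -2 -3 -4 -3  5  7 -2  5  3 -3 -2 -1 -2 -1  4
K -2  2  0 -1 -4  1  1 -2 -1 -4 -3  5 -2 -4 -1  0 -1 -3 -2 -3
M  1 -2 -3 -4  1 -1 -3 -4 -3  3  4 -2  7  2 -3 -2 -2 -2 -2  3
F  0 -4 -4 -4  0 -4 -4 -4 -2  2  2 -4  2  8 -5 -3 -3  0  2  1
P -2 -2 -2 -1 -4 -1 -1 -2 -2 -4 -4 -1 -3 -5  7 -1 -1 -4 -3 -3
S  0 -1  1  0 -2  0  0  0 -1 -3 -3  0 -2 -3 -1  4  1 -3 -2 -3
T -1 -1  0 -1 -2 -1 -1 -2 -2 -2 -2 -1 -2 -3 -1  1  5 -2 -2 -1
W -4 -3 -4 -4 -3 -2 -3 -2 -2 -4 -3 -3 -2  0 -4 -3 -2 11  2 -4
Y -3 -2 -2 -3 -3 -1 -2 -3  2 -2 -2 -2 -2  2 -3 -2 -2  2  7 -2
V  3 -3 -3 -3  2 -2 -2 -3 -3  6  4 -2  4  2 -2 -2  0 -3 -1  7
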