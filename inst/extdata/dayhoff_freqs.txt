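# Dayhoff amino-acid background frequencies (Dayhoff, Schwartz & Orcutt 1978).
# The printed values sum to 1.001; the loader renormalizes to 1.
A 0.087
R 0.041
N 0.040
D 0.047
C 0.033
Q 0.038
E 0.050
G 0.089
H 0.034
I 0.037
L 0.085
K 0.081
M 0.015
F 0.040
P 0.051
S 0.070
T 0.058
W 0.010
Y 0.030
V 0.065
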