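# PAM60 log-odds matrix, generated from the Dayhoff PAM1 mutation
# probability model (half-bit units, rounded). Generated table, not the
# NCBI distribution file.
    A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   Y   V
A   5  -5  -2  -2  -5  -3  -1   0  -5  -3  -4  -5  -3  -6   0   1   1 -10  -6  -1
R  -5   8  -3  -7  -6   0  -6  -7   0  -4  -6   2  -3  -6  -2  -2  -4   0  -9  -5
N  -2  -3   6   2  -7  -2   0  -1   1  -4  -5   0  -6  -5  -3   1  -1  -7  -3  -5
D  -2  -7   2   7 -10  -1   3  -2  -2  -5  -9  -3  -8 -10  -5  -2  -3 -12  -8  -6
C  -5  -6  -7 -10   9 -10 -10  -8  -5  -4 -11 -10 -10  -9  -5  -2  -5 -11  -2  -4
Q  -3   0  -2  -1 -10   7   2  -5   2  -5  -3  -1  -2  -9  -1  -3  -4 -10  -8  -5
E  -1  -6   0   3 -10   2   7  -2  -3  -4  -6  -3  -6 -10  -3  -2  -4 -12  -6  -5
G   0  -7  -1  -2  -8  -5  -2   6  -7  -7  -7  -5  -7  -7  -4   0  -3 -11 -10  -4
H  -5   0   1  -2  -5   2  -3  -7   8  -7  -5  -4  -7  -4  -2  -4  -5  -7  -2  -5
I  -3  -4  -4  -5  -4  -5  -4  -7  -7   7   0  -4   1  -1  -6  -4  -1 -10  -4   3
L  -4  -6  -5  -9 -11  -3  -6  -7  -5   0   6  -6   2  -1  -5  -6  -4  -8  -5  -1
K  -5   2   0  -3 -10  -1  -3  -5  -4  -4  -6   6   0 -10  -4  -2  -2  -8  -9  -6
M  -3  -3  -6  -8 -10  -2  -6  -7  -7   1   2   0  10  -3  -6  -4  -2 -10  -8   0
F  -6  -6  -5 -10  -9  -9 -10  -7  -4  -1  -1 -10  -3   8  -8  -5  -6  -2   3  -5
P   0  -2  -3  -5  -5  -1  -3  -4  -2  -6  -5  -4  -6  -8   7   0  -2 -10 -10  -4
S   1  -2   1  -2  -2  -3  -2   0  -4  -4  -6  -2  -4  -5   0   5   1  -3  -5  -4
T   1  -4  -1  -3  -5  -4  -4  -3  -5  -1  -4  -2  -2  -6  -2   1   6  -9  -5  -1
W -10   0  -7 -12 -11 -10 -12 -11  -7 -10  -8  -8 -10  -2 -10  -3  -9  13  -2 -12
Y  -6  -9  -3  -8  -2  -8  -6 -10  -2  -4  -5  -9  -8   3 -10  -5  -5  -2   9  -5
V  -1  -5  -5  -6  -4  -5  -5  -4  -5   3  -1  -6   0  -5  -4  -4  -1 -12  -5   6
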