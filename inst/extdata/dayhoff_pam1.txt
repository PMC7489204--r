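# Dayhoff PAM1 mutation probability matrix (Dayhoff, Schwartz & Orcutt 1978,
# "Atlas of Protein Sequence and Structure" vol. 5 suppl. 3).
# Entries are probabilities x 10^4. Element (row i, column j) is the
# probability that the amino acid in column j is replaced by the amino acid
# in row i after one PAM of evolution; columns sum to 10^4 up to the
# rounding of the printed table. The loader transposes to row-stochastic
# orientation and renormalizes rows.
   A    R    N    D    C    Q    E    G    H    I    L    K    M    F    P    S    T    W    Y    V
A 9867    2    9   10    3    8   17   21    2    6    4    2    6    2   22   35   32    0    2   18
R    1 9913    1    0    1   10    0    0   10    3    1   19    4    1    4    6    1    8    0    1
N    4    1 9822   36    0    4    6    6   21    3    1   13    0    1    2   20    9    1    4    1
D    6    0   42 9859    0    6   53    6    4    1    0    3    0    0    1    5    3    0    0    1
C    1    1    0    0 9973    0    0    0    1    1    0    0    0    0    1    5    1    0    3    2
Q    3    9    4    5    0 9876   27    1   23    1    3    6    4    0    6    2    2    0    0    1
E   10    0    7   56    0   35 9865    4    2    3    1    4    1    0    3    4    2    0    1    2
G   21    1   12   11    1    3    7 9935    1    0    1    2    1    1    3   21    3    0    0    5
H    1    8   18    3    1   20    1    0 9912    0    1    1    0    2    3    1    1    1    4    1
I    2    2    3    1    2    1    2    0    0 9872    9    2   12    7    0    1    7    0    1   33
L    3    1    3    0    0    6    1    1    4   22 9947    2   45   13    3    1    3    4    2   15
K    2   37   25    6    0   12    7    2    2    4    1 9926   20    0    3    8   11    0    1    1
M    1    1    0    0    0    2    0    0    0    5    8    4 9874    1    0    1    2    0    0    4
F    1    1    1    0    0    0    0    1    2    8    6    0    4 9946    0    2    1    3   28    0
P   13    5    2    1    1    8    3    2    5    1    2    2    1    1 9926   12    4    0    0    2
S   28   11   34    7   11    4    6   16    2    2    1    7    4    3   17 9840   38    5    2    2
T   22    2   13    4    1    3    2    2    1   11    2    8    6    1    5   32 9871    0    2    9
W    0    2    0    0    0    0    0    0    0    0    0    0    0    1    0    1    0 9976    1    0
Y    1    0    3    0    3    0    1    0    4    1    1    0    0   21    0    1    1    2 9945    1
V   13    2    1    1    3    2    2    3    3   57   11    1   17    1    3    2   10    0    2 9901
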