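# Molecular volume of the 20 canonical amino acid residues (A^3).
# Grantham (1974) Science 185:862-864 volume property, as used by
# Haig & Hurst (1991) for genetic-code error analysis.
aa	value
A	31
R	124
N	56
D	54
C	55
Q	85
E	83
G	3
H	96
I	111
L	111
K	119
M	105
F	132
P	32.5
S	32
T	61
W	170
Y	136
V	84
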