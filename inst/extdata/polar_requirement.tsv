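# Polar requirement of the 20 canonical amino acids.
# Chromatographic polarity scale of Woese et al. (1966), as used by
# Haig & Hurst (1991) J Mol Evol 33:412-417 for genetic-code error analysis.
aa	value
A	7.0
R	9.1
N	10.0
D	13.0
C	4.8
Q	8.6
E	12.5
G	7.9
H	8.4
I	4.9
L	4.9
K	10.1
M	5.3
F	5.0
P	6.6
S	7.5
T	6.6
W	5.2
Y	5.4
V	5.6
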