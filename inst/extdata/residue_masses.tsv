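entry	type	formula	monoisotopic_mass
G	residue	C2H3NO	57.021464
A	residue	C3H5NO	71.037114
S	residue	C3H5NO2	87.032028
P	residue	C5H7NO	97.052764
V	residue	C5H9NO	99.068414
T	residue	C4H7NO2	101.047678
C	residue	C3H5NOS	103.009185
L	residue	C6H11NO	113.084064
I	residue	C6H11NO	113.084064
N	residue	C4H6N2O2	114.042927
D	residue	C4H5NO3	115.026943
Q	residue	C5H8N2O2	128.058578
K	residue	C6H12N2O	128.094963
E	residue	C5H7NO3	129.042593
M	residue	C5H9NOS	131.040485
H	residue	C6H7N3O	137.058912
F	residue	C9H9NO	147.068414
R	residue	C6H12N4O	156.101111
Y	residue	C9H9NO2	163.063329
W	residue	C11H10N2O	186.079313
carbamidomethyl-C	modification	+C2H3NO	57.021464
oxidation-M	modification	+O	15.994915
acetyl-Nterm	modification	+C2H2O	42.010565
NEM-C	modification	+C6H7NO2	125.047679
water	constant	H2O	18.010565
proton	constant	H+	1.007276
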