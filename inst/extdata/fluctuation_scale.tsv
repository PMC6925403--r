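# Fluctuation classification of the 20 standard amino acids with the
# integer fluctuation index and the carbon content of each residue as
# a chain monomer (free amino acid minus one water; hydrogens counted).
residue	class	index	carbon_atoms	total_atoms
A	high	-2	3	10
C	moderate	-1	3	11
D	high	-2	4	13
E	moderate	-1	5	16
F	weak	2	9	20
G	high	-2	2	7
H	weak	2	6	17
I	weak	2	6	19
K	moderate	-1	6	21
L	weak	2	6	19
M	weak	2	5	17
N	moderate	-1	4	14
P	high	-2	5	14
Q	moderate	-1	5	17
R	moderate	-1	6	23
S	high	-2	3	11
T	moderate	-1	4	14
V	moderate	-1	5	16
W	weak	2	11	24
Y	weak	2	9	21
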