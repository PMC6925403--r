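HEADER    SYNTHETIC RENDERING OF CROTAMINE SEQUENCE
REMARK   9 SYNTHETIC MINIMAL PDB: SEQRES + PLACEHOLDER CA ATOMS ONLY
SEQRES   1 A   42  TYR LYS GLN CYS HIS LYS LYS GLY GLY HIS CYS PHE PRO
SEQRES   2 A   42  LYS GLU LYS ILE CYS LEU PRO PRO SER SER ASP PHE GLY
SEQRES   3 A   42  LYS MET ASP CYS ARG TRP ARG TRP LYS CYS CYS LYS LYS
SEQRES   4 A   42  GLY SER GLY
ATOM      1  CA  TYR A   1       3.800   0.000   0.000  1.00  0.00           C
ATOM      2  CA  LYS A   2       7.600   0.000   0.000  1.00  0.00           C
ATOM      3  CA  GLN A   3      11.400   0.000   0.000  1.00  0.00           C
ATOM      4  CA  CYS A   4      15.200   0.000   0.000  1.00  0.00           C
ATOM      5  CA  HIS A   5      19.000   0.000   0.000  1.00  0.00           C
ATOM      6  CA  LYS A   6      22.800   0.000   0.000  1.00  0.00           C
ATOM      7  CA  LYS A   7      26.600   0.000   0.000  1.00  0.00           C
ATOM      8  CA  GLY A   8      30.400   0.000   0.000  1.00  0.00           C
ATOM      9  CA  GLY A   9      34.200   0.000   0.000  1.00  0.00           C
ATOM     10  CA  HIS A  10      38.000   0.000   0.000  1.00  0.00           C
ATOM     11  CA  CYS A  11      41.800   0.000   0.000  1.00  0.00           C
ATOM     12  CA  PHE A  12      45.600   0.000   0.000  1.00  0.00           C
ATOM     13  CA  PRO A  13      49.400   0.000   0.000  1.00  0.00           C
ATOM     14  CA  LYS A  14      53.200   0.000   0.000  1.00  0.00           C
ATOM     15  CA  GLU A  15      57.000   0.000   0.000  1.00  0.00           C
ATOM     16  CA  LYS A  16      60.800   0.000   0.000  1.00  0.00           C
ATOM     17  CA  ILE A  17      64.600   0.000   0.000  1.00  0.00           C
ATOM     18  CA  CYS A  18      68.400   0.000   0.000  1.00  0.00           C
ATOM     19  CA  LEU A  19      72.200   0.000   0.000  1.00  0.00           C
ATOM     20  CA  PRO A  20      76.000   0.000   0.000  1.00  0.00           C
ATOM     21  CA  PRO A  21      79.800   0.000   0.000  1.00  0.00           C
ATOM     22  CA  SER A  22      83.600   0.000   0.000  1.00  0.00           C
ATOM     23  CA  SER A  23      87.400   0.000   0.000  1.00  0.00           C
ATOM     24  CA  ASP A  24      91.200   0.000   0.000  1.00  0.00           C
ATOM     25  CA  PHE A  25      95.000   0.000   0.000  1.00  0.00           C
ATOM     26  CA  GLY A  26      98.800   0.000   0.000  1.00  0.00           C
ATOM     27  CA  LYS A  27     102.600   0.000   0.000  1.00  0.00           C
ATOM     28  CA  MET A  28     106.400   0.000   0.000  1.00  0.00           C
ATOM     29  CA  ASP A  29     110.200   0.000   0.000  1.00  0.00           C
ATOM     30  CA  CYS A  30     114.000   0.000   0.000  1.00  0.00           C
ATOM     31  CA  ARG A  31     117.800   0.000   0.000  1.00  0.00           C
ATOM     32  CA  TRP A  32     121.600   0.000   0.000  1.00  0.00           C
ATOM     33  CA  ARG A  33     125.400   0.000   0.000  1.00  0.00           C
ATOM     34  CA  TRP A  34     129.200   0.000   0.000  1.00  0.00           C
ATOM     35  CA  LYS A  35     133.000   0.000   0.000  1.00  0.00           C
ATOM     36  CA  CYS A  36     136.800   0.000   0.000  1.00  0.00           C
ATOM     37  CA  CYS A  37     140.600   0.000   0.000  1.00  0.00           C
ATOM     38  CA  LYS A  38     144.400   0.000   0.000  1.00  0.00           C
ATOM     39  CA  LYS A  39     148.200   0.000   0.000  1.00  0.00           C
ATOM     40  CA  GLY A  40     152.000   0.000   0.000  1.00  0.00           C
ATOM     41  CA  SER A  41     155.800   0.000   0.000  1.00  0.00           C
ATOM     42  CA  GLY A  42     159.600   0.000   0.000  1.00  0.00           C
TER
END
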