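ATOM      1 CA   ALA H  28       6.000   0.000   0.000  1.00  0.00           C
ATOM      2 CB   ALA H  28       6.900   0.900   0.900  1.00  0.00           C
ATOM      3 CA   ALA H  29       5.638   2.052   0.000  1.00  0.00           C
ATOM      4 CB   ALA H  29       6.538   2.952   0.900  1.00  0.00           C
ATOM      5 CA   ALA H  30       4.596   3.857   0.000  1.00  0.00           C
ATOM      6 CB   ALA H  30       5.496   4.757   0.900  1.00  0.00           C
ATOM      7 CA   ALA H  31       3.000   5.196   0.000  1.00  0.00           C
ATOM      8 CB   ALA H  31       3.900   6.096   0.900  1.00  0.00           C
ATOM      9 CA   ALA H  32       1.042   5.909   0.000  1.00  0.00           C
ATOM     10 CB   ALA H  32       1.942   6.809   0.900  1.00  0.00           C
ATOM     11 CA   ALA H  33      -1.042   5.909   0.000  1.00  0.00           C
ATOM     12 CB   ALA H  33      -0.142   6.809   0.900  1.00  0.00           C
ATOM     13 CA   ALA H  34      -3.000   5.196   0.000  1.00  0.00           C
ATOM     14 CB   ALA H  34      -2.100   6.096   0.900  1.00  0.00           C
ATOM     15 CA   ALA H  35      -4.596   3.857   0.000  1.00  0.00           C
ATOM     16 CB   ALA H  35      -3.696   4.757   0.900  1.00  0.00           C
ATOM     17 CA   ALA H  36      -5.638   2.052   0.000  1.00  0.00           C
ATOM     18 CB   ALA H  36      -4.738   2.952   0.900  1.00  0.00           C
ATOM     19 CA   ALA H  37      -6.000   0.000   0.000  1.00  0.00           C
ATOM     20 CB   ALA H  37      -5.100   0.900   0.900  1.00  0.00           C
ATOM     21 CA   ALA H 100       6.000   0.000   5.000  1.00  0.00           C
ATOM     22 CB   ALA H 100       6.900   0.900   5.900  1.00  0.00           C
ATOM     23 CA   ALA H 101       5.638   2.052   5.000  1.00  0.00           C
ATOM     24 CB   ALA H 101       6.538   2.952   5.900  1.00  0.00           C
ATOM     25 CA   ALA H 102       4.596   3.857   5.000  1.00  0.00           C
ATOM     26 CB   ALA H 102       5.496   4.757   5.900  1.00  0.00           C
ATOM     27 CA   ALA H 103       3.000   5.196   5.000  1.00  0.00           C
ATOM     28 CB   ALA H 103       3.900   6.096   5.900  1.00  0.00           C
ATOM     29 CA   ALA H 104       1.042   5.909   5.000  1.00  0.00           C
ATOM     30 CB   ALA H 104       1.942   6.809   5.900  1.00  0.00           C
ATOM     31 CA   ALA H 105      -1.042   5.909   5.000  1.00  0.00           C
ATOM     32 CB   ALA H 105      -0.142   6.809   5.900  1.00  0.00           C
ATOM     33 CA   ALA H 106      -3.000   5.196   5.000  1.00  0.00           C
ATOM     34 CB   ALA H 106      -2.100   6.096   5.900  1.00  0.00           C
ATOM     35 CA   ALA H 107      -4.596   3.857   5.000  1.00  0.00           C
ATOM     36 CB   ALA H 107      -3.696   4.757   5.900  1.00  0.00           C
ATOM     37 CA   ALA H 108      -5.638   2.052   5.000  1.00  0.00           C
ATOM     38 CB   ALA H 108      -4.738   2.952   5.900  1.00  0.00           C
ATOM     39 CA   ALA H 109      -6.000   0.000   5.000  1.00  0.00           C
ATOM     40 CB   ALA H 109      -5.100   0.900   5.900  1.00  0.00           C
HETATM   41 C1   FLU L 500       0.000   7.500   5.000  1.00  0.00           C
HETATM   42 C2   FLU L 500       1.400   7.500   5.000  1.00  0.00           C
HETATM   43 O1   FLU L 500       2.400   7.500   5.000  1.00  0.00           O
END
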