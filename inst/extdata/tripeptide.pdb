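MODEL        1
ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N
ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C
ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C
ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O
ATOM      5  CB  ALA A   1       2.000  -0.773   1.207  1.00  0.00           C
ATOM      6  N   GLY A   2       3.332   1.536   0.062  1.00  0.00           N
ATOM      7  CA  GLY A   2       3.974   2.840   0.110  1.00  0.00           C
ATOM      8  C   GLY A   2       5.478   2.711   0.230  1.00  0.00           C
ATOM      9  O   GLY A   2       6.020   1.610   0.330  1.00  0.00           O
ATOM     10  N   SER A   3       6.170   3.845   0.215  1.00  0.00           N
ATOM     11  CA  SER A   3       7.618   3.880   0.318  1.00  0.00           C
ATOM     12  C   SER A   3       8.250   5.237   0.120  1.00  0.00           C
ATOM     13  O   SER A   3       7.570   6.260   0.090  1.00  0.00           O
ATOM     14  CB  SER A   3       8.210   2.900   1.340  1.00  0.00           C
ATOM     15  OG  SER A   3       7.790   1.560   1.120  1.00  0.00           O
ENDMDL
MODEL        2
ATOM      1  N   ALA A   1       0.050   0.020  -0.030  1.00  0.00           N
ATOM      2  CA  ALA A   1       1.500   0.030  -0.020  1.00  0.00           C
ATOM      3  C   ALA A   1       2.060   1.440  -0.010  1.00  0.00           C
ATOM      4  O   ALA A   1       1.300   2.420  -0.020  1.00  0.00           O
ATOM      5  CB  ALA A   1       2.040  -0.750   1.190  1.00  0.00           C
ATOM      6  N   GLY A   2       3.380   1.550   0.050  1.00  0.00           N
ATOM      7  CA  GLY A   2       4.020   2.860   0.100  1.00  0.00           C
ATOM      8  C   GLY A   2       5.520   2.730   0.220  1.00  0.00           C
ATOM      9  O   GLY A   2       6.060   1.630   0.320  1.00  0.00           O
ATOM     10  N   SER A   3       6.210   3.860   0.200  1.00  0.00           N
ATOM     11  CA  SER A   3       7.660   3.900   0.300  1.00  0.00           C
ATOM     12  C   SER A   3       8.290   5.260   0.110  1.00  0.00           C
ATOM     13  O   SER A   3       7.610   6.280   0.080  1.00  0.00           O
ATOM     14  CB  SER A   3       8.250   2.920   1.330  1.00  0.00           C
ATOM     15  OG  SER A   3       7.830   1.580   1.110  1.00  0.00           O
ENDMDL
END
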