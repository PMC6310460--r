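HETATM    1  PA  GDP X   1      -1.971  -0.480  -2.073  1.00  0.00           P
HETATM    2  PB  GDP X   1       0.000   0.000   0.000  1.00  0.00           P
HETATM    3  O1A GDP X   1      -3.015   0.437  -1.508  1.00  0.00           O
HETATM    4  O2A GDP X   1      -2.276  -1.893  -1.672  1.00  0.00           O
HETATM    5  O3A GDP X   1      -0.533  -0.063  -1.507  1.00  0.00           O
HETATM    6  O1B GDP X   1      -0.500  -1.194   0.758  1.00  0.00           O
HETATM    7  O2B GDP X   1      -0.500   1.253   0.655  1.00  0.00           O
HETATM    8  O3B GDP X   1       1.600   0.000   0.000  1.00  0.00           O
HETATM    9  O5' GDP X   1      -1.969  -0.367  -3.669  1.00  0.00           O
HETATM   10  AL  ALF X   2       2.757   1.105   0.000  1.00  0.00          AL
HETATM   11  F1  ALF X   2       2.757   1.105  -1.690  1.00  0.00           F
HETATM   12  F2  ALF X   2       1.589   2.327   0.000  1.00  0.00           F
HETATM   13  F3  ALF X   2       2.757   1.105   1.690  1.00  0.00           F
HETATM   14  F4  ALF X   2       3.924  -0.116   0.000  1.00  0.00           F
HETATM   15  MG   MG M   1       1.395   1.415  -0.162  1.00  0.00          MG
HETATM   16  K     K C   1      -0.665   1.934  -1.234  1.00  0.00           K
ATOM     17  N   LYS P  25       3.767   2.192   9.569  1.00  0.00           N
ATOM     18  CA  LYS P  25       2.313   2.167   9.438  1.00  0.00           C
ATOM     19  C   LYS P  25       2.400   3.677   9.587  1.00  0.00           C
ATOM     20  O   LYS P  25       2.644   3.902  10.771  1.00  0.00           O
ATOM     21  CB  LYS P  25       2.016   1.893   7.993  1.00  0.00           C
ATOM     22  CG  LYS P  25       1.718   1.618   6.549  1.00  0.00           C
ATOM     23  CD  LYS P  25       1.421   1.344   5.105  1.00  0.00           C
ATOM     24  CE  LYS P  25       1.123   1.070   3.660  1.00  0.00           C
ATOM     25  NZ  LYS P  25       0.826   0.795   2.216  1.00  0.00           N
END
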