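H KYTJ820101
D Hydropathy index (Kyte-Doolittle, 1982)
R
A Kyte, J. and Doolittle, R.F.
T A simple method for displaying the hydropathic character of a protein
J J. Mol. Biol. 157, 105-132 (1982)
C
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     1.800  -4.500  -3.500  -3.500   2.500  -3.500  -3.500  -0.400  -3.200   4.500
     3.800  -3.900   1.900   2.800  -1.600  -0.800  -0.700  -0.900  -1.300   4.200
//
H HOPT810101
D Hydrophilicity value (Hopp-Woods, 1981)
R
A Hopp, T.P. and Woods, K.R.
T Prediction of protein antigenic determinants from amino acid sequences
J Proc. Natl. Acad. Sci. USA 78, 3824-3828 (1981)
C
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    -0.500   3.000   0.200   3.000  -1.000   0.200   3.000   0.000  -0.500  -1.800
    -1.800   3.000  -1.300  -2.500   0.000   0.300  -0.400  -3.400  -2.300  -1.500
//
H SYNFLX0001
D Synthetic flexibility-like scale 1 (generated; not an AAindex entry)
R
A flucres authors
T Deterministic synthetic scale for exercising the rank-matrix builder
J unpublished
C
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     0.407   0.217   0.505   0.875  -0.585  -0.363  -0.306   1.562  -1.197  -1.533
    -1.297   0.813  -0.576  -1.260   1.019   1.733  -0.179  -0.629  -0.312  -0.281
//
H SYNFLX0002
D Synthetic flexibility-like scale 2 (generated; not an AAindex entry)
R
A flucres authors
T Deterministic synthetic scale for exercising the rank-matrix builder
J unpublished
C
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    -0.017  -0.289   0.121   1.014  -0.050   0.267   0.252   2.535  -0.674  -1.879
    -1.363  -0.805  -1.626  -1.067   0.733   0.868   0.819  -1.430  -1.257  -0.798
//
H SYNFLX0003
D Synthetic flexibility-like scale 3 (generated; not an AAindex entry)
R
A flucres authors
T Deterministic synthetic scale for exercising the rank-matrix builder
J unpublished
C
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     1.047  -0.171  -0.854   1.216   0.513  -0.034   0.019   1.192  -0.388  -0.407
    -0.056   0.648  -1.455  -1.417   0.725   0.975  -1.469  -1.742  -1.459  -0.016
//
H SYNFLX0004
D Synthetic flexibility-like scale 4 (generated; not an AAindex entry)
R
A flucres authors
T Deterministic synthetic scale for exercising the rank-matrix builder
J unpublished
C
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     1.206  -1.392   0.472   1.594   0.418  -1.271   0.919   1.792  -1.466  -0.279
    -1.808   0.564  -1.085   0.333   0.586   0.386   0.014  -0.512  -1.046  -1.198
//
H SYNFLX0005
D Synthetic flexibility-like scale 5 (generated; not an AAindex entry)
R
A flucres authors
T Deterministic synthetic scale for exercising the rank-matrix builder
J unpublished
C
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     0.546  -0.411   0.224   0.952  -0.291  -0.507   0.168   0.480  -1.928  -0.635
    -1.430  -0.602  -1.150  -1.966  -0.019   1.657  -0.144  -0.973  -0.751  -1.107
//
H SYNFLX0006
D Synthetic flexibility-like scale 6 (generated; not an AAindex entry)
R
A flucres authors
T Deterministic synthetic scale for exercising the rank-matrix builder
J unpublished
C
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     1.395  -0.870  -0.243   1.528   0.369   0.154   1.158   1.473  -0.905  -1.591
    -2.234  -1.004   0.833  -1.828   0.783   0.092   0.159  -1.078  -0.304  -0.398
//
H SYNFLX0007
D Synthetic flexibility-like scale 7 (generated; not an AAindex entry)
R
A flucres authors
T Deterministic synthetic scale for exercising the rank-matrix builder
J unpublished
C
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     0.997  -0.913  -0.672   0.906  -0.367  -0.104  -0.088   1.952  -1.302  -0.211
    -0.887  -0.208  -1.266   0.079   0.549   1.368   0.848  -0.860  -1.110  -0.149
//
H SYNFLX0008
D Synthetic flexibility-like scale 8 (generated; not an AAindex entry)
R
A flucres authors
T Deterministic synthetic scale for exercising the rank-matrix builder
J unpublished
C
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     0.383  -0.546   0.325   0.344  -0.043  -0.245   1.369   0.828  -1.328   0.228
    -1.430   0.527  -1.142  -1.131   0.831   1.266  -0.492  -0.931  -0.204  -0.130
//
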