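# Broth-microdilution MICs (ug/mL) of compounds 2a-2f; two-fold ladder
# 78-1250 ug/mL; NT = not tested.
organism,class,2a,2b,2c,2d,2e,2f
B. cereus,Gram-positive,625,625,625,625,1250,625
B. subtilis,Gram-positive,625,625,625,312,625,312
Y. pseudotuberculosis,Gram-negative,625,625,625,625,625,625
K. pneumoniae,Gram-negative,625,625,625,312,1250,156
E. coli,Gram-negative,625,625,625,625,1250,625
P. aeruginosa,Gram-negative,625,625,625,625,625,625
S. aureus,Gram-positive,625,312,625,625,1250,312
E. faecalis,Gram-positive,625,625,625,625,625,625
C. albicans,Fungal,156,312,156,78,1250,78
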