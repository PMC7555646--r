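name	pattern	both_strands
ABRE	ACGTG	TRUE
G-box	CACGTG	TRUE
W-box	TTGACY	TRUE
as-1	TGACG	FALSE
CGTCA-motif	CGTCA	FALSE
MBS	CAACTG	TRUE
TATC-box	TATCCCA	TRUE
GC-motif	CCCCCG	TRUE
TC-rich	ATTTTCTTCA	TRUE
AuxRR-core	GGTCCAT	TRUE
GARE-motif	TCTGTTG	TRUE
P-box	CCTTTTG	TRUE
TGA-element	AACGAC	TRUE
TATA-box	TATAAA	FALSE
CAAT-box	CCAAT	FALSE
LTR	CCGAAA	TRUE
ERE	ATTTCAAA	TRUE
HSE	AAAAAATTTC	TRUE
ARE	AAACCA	TRUE
Skn-1	GTCAT	FALSE
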