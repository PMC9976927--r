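factor	provenance
POLR2A	go
POLR2B	go
POLR2G	go
POLR2H	go
MLLT1	literature
SUPT5H	literature
GTF2F1	go
BRD4	literature
WDR43	go
NCBP2	go
HNRNPU	go
LARP7	literature
MYC	literature
TAF1	literature
TBP	literature
AFF1	literature
EZH2	go
PAF1	literature
SSRP1	go
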