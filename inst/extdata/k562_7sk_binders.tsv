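factor	status
LARP7	known
AQR	novel
SSB	novel
HNRNPK	novel
DGCR8	novel
PCBP1	novel
ATF	novel
ZNF800	novel
XRCC6	novel
NCBP2	novel
SBDS	novel
YWHAG	novel
GRWD1	novel
ZNF622	novel
SRSF7	novel
TARDBP	novel
BUD13	novel
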