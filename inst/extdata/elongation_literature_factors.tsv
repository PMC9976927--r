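factor	group
CCNT1	super_elongation_complex
CCNT2	super_elongation_complex
ELL	super_elongation_complex
ELL2	super_elongation_complex
ELL3	super_elongation_complex
AFF1	super_elongation_complex
AFF4	super_elongation_complex
MLLT1	super_elongation_complex
MLLT3	super_elongation_complex
NELFA	pausing
NELFB	pausing
NELFCD	pausing
NELFE	pausing
SUPT4H1	pausing
SUPT5H	pausing
SUPT6H	pausing
SUPT16H	pausing
BRD4	pausing
MYC	pausing
TAF1	pausing
TBP	pausing
PAF1	pausing
CDK9	pausing
LARP7	7sk_snrnp
HEXIM1	7sk_snrnp
HEXIM2	7sk_snrnp
MEPCE	7sk_snrnp
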