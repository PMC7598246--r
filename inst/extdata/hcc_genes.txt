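# Genes with literature support for a role in hepatocellular carcinoma
# (disease-association input for the prioritization ledger).
SRC
SYK
AR
TUBB1
CDK4
CDK6
TYMS
ESR1
FGFR1
FGFR2
VEGFR2
TGFB2
HIF1A
ICAM1
ETS1
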