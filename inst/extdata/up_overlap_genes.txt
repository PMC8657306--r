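CST1
FILIP1L
CHST1
ALCAM
EPHA4
KRT8
ELF3
KRT18
SLC1A1
PCP4
ASS1
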