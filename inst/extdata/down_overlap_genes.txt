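LOXL3
FOXL1
RRAD
ST6GALNAC5
CCL25
IGFBP3
C1QL4
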