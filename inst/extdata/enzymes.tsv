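name	recognition	cut_offset	remnant	methylation_sensitive
PstI	CTGCAG	1	TGCAG	yes
EcoT22I	ATGCAT	1	TGCAT	no
ApeKI	GCWGC	1	CWGC	yes
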