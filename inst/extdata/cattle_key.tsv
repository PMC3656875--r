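sample	barcode	breed	blank
HOL01	TGACGCCA	Holstein	0
HOL02	CAGATA	Holstein	0
HOL03	GAAGTG	Holstein	0
HOL04	TAGCGGAT	Holstein	0
HOL05	TATTCGCAT	Holstein	0
HOL06	ATAGAT	Holstein	0
ANG01	CCGAACA	Angus	0
ANG02	GGAAGACAT	Angus	0
ANG03	GGCTTA	Angus	0
ANG04	AACGCACATT	Angus	0
ANG05	GAGCGACAT	Angus	0
ANG06	CCTTGCCATT	Angus	0
HER01	GGTATA	Hereford	0
HER02	TCTTGG	Hereford	0
HER03	GGTGT	Hereford	0
BRG01	GGATA	Brangus	0
BRG02	CTAAGCA	Brangus	0
BRG03	ATTAT	Brangus	0
BRG04	GCGCTCA	Brangus	0
BRG05	ACTGCGAT	Brangus	0
BRG06	TTCGTT	Brangus	0
BRG07	ATATAA	Brangus	0
BRG08	TGGCAACAGA	Brangus	0
BRG09	CTCGTCG	Brangus	0
BRG10	GCCTACCT	Brangus	0
BRG11	CACCA	Brangus	0
BRG12	AATTAG	Brangus	0
BRG13	GGAACGA	Brangus	0
BRG14	ACAACT	Brangus	0
BRG15	ACTGCT	Brangus	0
BRG16	CGTGGACAGT	Brangus	0
BRG17	TGGCACAGA	Brangus	0
BRG18	TGCTT	Brangus	0
BRG19	GCAAGCCAT	Brangus	0
BRG20	CGCACCAATT	Brangus	0
BRG21	CTCGCGG	Brangus	0
BRG22	AACTGG	Brangus	0
BRG23	ATGAGCAA	Brangus	0
BRG24	CTTGA	Brangus	0
BRG25	GCGTCCT	Brangus	0
BRG26	ACCAGGA	Brangus	0
BRG27	CCACTCA	Brangus	0
WFU01	TCACGGAAG	WhiteFulani	0
WFU02	TATCA	WhiteFulani	0
MUT01	TAGCCAA	Muturu	0
MUT02	ATATCGCCA	Muturu	0
MUT03	CTCTA	Muturu	0
BLANK	GGTGCACATT	none	1
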