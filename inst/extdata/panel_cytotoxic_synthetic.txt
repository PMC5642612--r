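ADORA2A
AMBP
ATG5
BATF
BCL2
C8A
C8B
CCL15
CCL23
CCL3
CD34
CD3E
CD46
CD59
CD63
CD70
CD86
CD8A
CR1
CSF3R
CTSW
CX3CL1
CXCR4
CXCR6
DMBT1
DOCK9
F2RL1
GZMH
HLA-A
ICOSLG
IDO1
IFNA7
IL12A
IL1RL1
IL1RN
IL22RA1
IL26
ITGA2B
ITGAX
ITGB1
KIR3DL2
LAMP2
MAGEA12
MAP2K1
MASP1
MYD88
NFKB1
NLRP3
PASD1
PBK
PECAM1
PLA2G6
POU2F2
PRF1
PRKCD
PSMB8
RAG1
RPS6
SMAD3
SMPD3
SYNCTX001
SYNCTX002
SYNCTX003
SYNCTX004
SYNCTX005
SYNCTX006
SYNCTX007
SYNCTX008
SYNCTX009
SYNCTX010
SYNCTX011
SYNCTX012
SYNCTX013
SYNCTX014
SYNCTX015
SYNCTX016
SYNCTX017
SYNCTX018
SYNCTX019
SYNCTX020
SYNCTX021
SYNCTX022
SYNCTX023
SYNCTX024
SYNCTX025
SYNCTX026
SYNCTX027
SYNCTX028
SYNCTX029
SYNCTX030
SYNCTX031
SYNCTX032
SYNCTX033
SYNCTX034
SYNCTX035
SYNCTX036
SYNCTX037
SYNCTX038
SYNCTX039
SYNCTX040
SYNCTX041
SYNCTX042
SYNCTX043
SYNCTX044
SYNCTX045
TGFB1
TIRAP
TLR3
TNFAIP3
TXK
TXNIP
TYK2
VCAM1
VEGFC
XCR1
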