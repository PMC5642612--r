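ATF1
ATG10
AXL
BCL2
BID
BIRC5
CCL14
CCL28
CCL7
CCR9
CD19
CD34
CDH5
CDK1
CSF3
CX3CR1
CXCL12
CXCR6
CYLD
DEFB1
F12
FYN
HAVCR2
IFNAR1
IFNB1
IL11
IL1R1
IL1RL1
IL28A
ITGA2
MS4A1
NLRC5
PDCD1
PDGFRB
PRKCD
ROPN1
SYNIFNA001
SYNIFNA002
SYNIFNA003
SYNIFNA004
SYNIFNA005
SYNIFNA006
SYNIFNA007
SYNIFNA008
SYNIFNA009
SYNIFNA010
SYNIFNA011
SYNIFNA012
SYNIFNA013
SYNIFNA014
SYNIFNA015
SYNIFNA016
SYNIFNA017
SYNIFNA018
SYNIFNA019
SYNIFNA020
SYNIFNA021
SYNIFNA022
SYNIFNA023
SYNIFNA024
SYNIFNA025
SYNIFNA026
SYNIFNA027
SYNIFNA028
SYNIFNA029
SYNIFNA030
SYNIFNA031
SYNIFNA032
SYNIFNA033
SYNIFNA034
SYNIFNA035
SYNIFNA036
SYNIFNA037
SYNIFNA038
SYNIFNA039
SYNIFNA040
SYNIFNA041
SYNIFNA042
SYNIFNA043
SYNIFNA044
SYNIFNA045
SYNIFNA046
SYNIFNA047
SYNIFNA048
SYNIFNA049
SYNIFNA050
SYNIFNA051
SYNIFNA052
SYNIFNA053
SYNIFNA054
SYNIFNA055
SYNIFNA056
SYNIFNA057
TICAM1
TLR4
TNFRSF1B
TXK
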