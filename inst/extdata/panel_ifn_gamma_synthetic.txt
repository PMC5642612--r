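A2M
ABL1
ADORA2A
BATF
BAX
BCL6
BLK
C3AR1
CCL20
CCL27
CCL5
CD160
CD200
CD27
CD33
CD4
CD59
CD6
CD70
CD8B
CD99
CEBPB
CMKLR1
COLEC12
CR1
CSF3
CSF3R
CT45A1
CTAGE1
CTCFL
CTSG
CTSW
CXCL10
CXCL11
CXCL16
CXCL5
CXCL6
CXCL9
CXCR3
DDX58
DEFB1
EBI3
EGR1
EGR2
EWSR1
F12
FEZ1
FN1
FPR2
GZMM
HLA-E
ICAM1
ICAM4
IFITM2
IFNB1
IGF2R
IL18
IL1RL1
IL2RG
IRF4
ITGA2
ITGAX
ITK
KIT
KLRB1
KLRD1
LAMP3
LCP1
LTBR
MAGEA4
MAGEB2
MAP2K2
MARCO
MICB
MME
NFATC1
NFATC3
NUP107
OSM
PDGFRB
POU2F2
PPARG
PSEN2
RPS6
S100A7
SERPINB2
SH2D1A
SPN
SPP1
SSX4
STAT4
SYK
SYNIFNG001
SYNIFNG002
SYNIFNG003
SYNIFNG004
SYNIFNG005
SYNIFNG006
SYNIFNG007
SYNIFNG008
SYNIFNG009
SYNIFNG010
SYNIFNG011
SYNIFNG012
SYNIFNG013
SYNIFNG014
SYNIFNG015
SYNIFNG016
SYNIFNG017
SYNIFNG018
SYNIFNG019
SYNIFNG020
SYNIFNG021
SYNIFNG022
SYNIFNG023
SYNIFNG024
SYNIFNG025
SYNIFNG026
SYNIFNG027
SYNIFNG028
SYNIFNG029
SYNIFNG030
SYNIFNG031
SYNIFNG032
SYNIFNG033
SYNIFNG034
SYNIFNG035
SYNIFNG036
SYNIFNG037
SYNIFNG038
SYNIFNG039
SYNIFNG040
SYNIFNG041
SYNIFNG042
SYNIFNG043
SYNIFNG044
SYNIFNG045
SYNIFNG046
SYNIFNG047
SYNIFNG048
SYNIFNG049
SYNIFNG050
SYNIFNG051
SYNIFNG052
SYNIFNG053
SYNIFNG054
SYNIFNG055
SYNIFNG056
SYNIFNG057
SYNIFNG058
SYNIFNG059
SYNIFNG060
SYNIFNG061
SYNIFNG062
SYNIFNG063
SYNIFNG064
SYNIFNG065
SYNIFNG066
SYNIFNG067
SYNIFNG068
SYNIFNG069
SYNIFNG070
SYNIFNG071
SYNIFNG072
SYNIFNG073
SYNIFNG074
SYNIFNG075
SYNIFNG076
SYNIFNG077
SYNIFNG078
SYNIFNG079
SYNIFNG080
SYNIFNG081
SYNIFNG082
SYNIFNG083
SYNIFNG084
SYNIFNG085
SYNIFNG086
SYNIFNG087
SYNIFNG088
SYNIFNG089
SYNIFNG090
SYNIFNG091
SYNIFNG092
SYNIFNG093
SYNIFNG094
SYNIFNG095
SYNIFNG096
SYNIFNG097
SYNIFNG098
SYNIFNG099
SYNIFNG100
TFRC
TGFB1
TGFB2
TICAM1
TIGIT
TLR8
TNFRSF11B
TTK
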