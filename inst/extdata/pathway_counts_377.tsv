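category	panther_id	K	k
JAK/STAT signaling pathway	P00038	17	6
Toll receptor signaling pathway	P00054	60	21
Interleukin signaling pathway	P00036	98	23
T cell activation	P00053	96	22
B cell activation	P00010	72	15
p38 MAPK pathway	P05918	42	7
Apoptosis signaling pathway	P00006	122	20
Inflammation mediated by chemokine and cytokine signaling pathway	P00031	261	36
Blood coagulation	P00011	47	6
VEGF signaling pathway	P00056	72	8
Ras Pathway	P04393	76	8
CCKR signaling map	P06959	173	17
p53 pathway	P00059	88	8
Angiogenesis	P00005	176	16
Integrin signalling pathway	P00034	192	17
EGF receptor signaling pathway	P00018	139	11
Gonadotropin-releasing hormone receptor pathway	P06664	235	15
Unclassified	UNCLASSIFIED	18333	232
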