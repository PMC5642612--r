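category	panther_id	K	k
JAK/STAT signaling pathway	P00038	17	3
Interleukin signaling pathway	P00036	98	9
B cell activation	P00010	72	6
Toll receptor signaling pathway	P00054	60	5
T cell activation	P00053	96	7
Inflammation mediated by chemokine and cytokine signaling pathway	P00031	261	12
Integrin signalling pathway	P00034	192	8
Unclassified	UNCLASSIFIED	18333	96
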