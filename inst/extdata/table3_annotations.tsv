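node	status	note
PGN	Altered
MDP	Altered
LPS	Altered
TLR2	Upregulated
TLR4	Upregulated
NOD2	Altered
NFkB	Altered
IL6	Upregulated
TNFa	Upregulated
TGFb	Upregulated
Th0	Unknown
Th0_M	Upregulated
IL18	Upregulated
IL1b	Upregulated
IFNg	Upregulated
IL23	Upregulated
IL22	Upregulated
IL21	Upregulated
IL17	Upregulated
IL10	Upregulated
Th17	Upregulated
Th17_M	Upregulated
Th1	Altered
Th2	Upregulated
IL4	Altered
IL15	Upregulated
IL12	Upregulated
IL13	Upregulated
Treg	Upregulated	Downregulated in blood, upregulated in mucosa
NK	Upregulated
DEF	Altered
IL2	Upregulated
MACR	Unknown
DC	Upregulated	Downregulated in blood, upregulated in mucosa
IEC_MICA_B	Upregulated
IEC_ULPB1_6	Upregulated
CD8_NKG2D	Upregulated
NK_NKG2D	Unknown
CD4_NKG2D	Upregulated
FIBROBLAST	Upregulated
PERFOR	Altered
GRANZB	Upregulated
MMPs	Upregulated
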