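feature_id	name	msi_level	esi_mode
liver_pos_0001	TAG 42:4	2	positive
liver_pos_0002	TAG 34:7	2	positive
liver_pos_0003	TAG 32:8	2	positive
liver_pos_0004	TAG 52:2	2	positive
liver_pos_0005	TAG 52:4	2	positive
liver_pos_0006	TAG 46:2	2	positive
liver_pos_0007	TAG 56:3	2	positive
liver_pos_0008	TAG 34:3	2	positive
liver_pos_0009	PC 16:1_16:0	2	positive
liver_pos_0010	PC 18:0_22:5	2	positive
liver_pos_0011	PC 16:0_18:2	2	positive
liver_pos_0012	PC 18:1_20:4	2	positive
liver_pos_0013	PC 16:0_18:1	2	positive
liver_pos_0014	PC 18:1_22:5	2	positive
liver_neg_0015	PE 18:1_18:1	2	negative
liver_neg_0016	PE 16:1_20:4	2	negative
liver_neg_0017	PE 18:1_22:5	2	negative
liver_neg_0018	PE 18:1_20:5	2	negative
liver_neg_0019	PE O-18:1_20:4	2	negative
liver_neg_0020	PE O-16:0_22:5	2	negative
liver_pos_0021	PC P-18:0_18:1	2	positive
liver_neg_0022	PS 44:5	2	negative
liver_neg_0023	PI 43:6	2	negative
liver_neg_0024	PG 40:6	2	negative
liver_pos_0025	LPC 17:0	2	positive
liver_pos_0026	LPC 16:1	2	positive
liver_neg_0027	LPE 26:1	2	negative
liver_pos_0028	SM d42:3	2	positive
liver_pos_0029	SM d31:2	2	positive
liver_pos_0030	SM d36:3	2	positive
liver_neg_0031	Cer C21:1	2	negative
liver_neg_0032	Cer C23:1	2	negative
liver_neg_0033	HexCer d37:3	2	negative
liver_pos_0034	Car 26:1	2	positive
liver_pos_0035	Car 12:1	2	positive
liver_pos_0036	CE 26:1	2	positive
liver_neg_0037	FFA 14:0	2	negative
liver_pos_0038	DAG 35:6	2	positive
liver_pos_0039	DAG 37:3	2	positive
liver_pos_0040	NAE 18:2	2	positive
liver_neg_0041	PC 16:1_16:0	2	negative
liver_neg_0042	PC 18:0_22:5	2	negative
liver_neg_0043	PC 16:0_18:2	2	negative
liver_neg_0044	PC 18:1_20:4	2	negative
liver_neg_0045	PC 16:0_18:1	2	negative
liver_neg_0046	PC 18:1_22:5	2	negative
liver_pos_0047	TAG 15:0_18:1_15:0(d7)	1	positive
liver_pos_0048	PC 15:0_18:1(d7)	1	positive
liver_neg_0049	PE 15:0_18:1(d7)	1	negative
liver_neg_0050	PE O-16:0_18:1(d7)	1	negative
liver_pos_0051	PC O-16:0_18:1(d7)	1	positive
liver_neg_0052	PS 15:0_18:1(d7)	1	negative
liver_neg_0053	PI 15:0_18:1(d7)	1	negative
liver_neg_0054	PG 15:0_18:1(d7)	1	negative
liver_pos_0055	LPC 18:1(d7)	1	positive
liver_neg_0056	LPE 18:1(d7)	1	negative
liver_pos_0057	SM d36:1(d9)	1	positive
liver_neg_0058	Cer C17:0(d7)	1	negative
liver_neg_0059	HexCer d35:1(d7)	1	negative
liver_pos_0060	Car 16:0(d7)	1	positive
liver_pos_0061	CE 18:1(d7)	1	positive
liver_neg_0062	FFA 17:0(d7)	1	negative
liver_pos_0063	DAG 15:0_18:1(d7)	1	positive
liver_pos_0064	NAE 16:0(d7)	1	positive
liver_pos_0065	unknown_001	4	positive
liver_pos_0066	unknown_002	4	positive
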