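id_a	id_b	Ka	Ks	type
OsYSL15	OsYSL2	0.1546	0.9061	tandem
OsYSL16	OsYSL15	0.1679	0.8115	segmental
OsYSL9	OsYSL2	0.1955	0.9902	segmental
OsYSL12	OsYSL13	0.3304	0.1368	tandem
OsOPT4	OsOPT3	0.1139	0.6271	tandem
OsOPT4	OsOPT2	0.0791	0.5929	tandem
OsOPT6	OsOPT8	0.5302	0.2936	segmental
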