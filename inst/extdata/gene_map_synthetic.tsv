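id	chrom	start	end	strand	rank
OsOPT1	chr1	87860001	87864000	+	4394
OsYSL2	chr2	86720001	86724000	+	4337
OsYSL15	chr2	86800001	86804000	+	4341
OsOPT8	chr2	93680001	93684000	+	4685
OsOPT7	chr3	107980001	107984000	+	5400
OsYSL13	chr4	88580001	88584000	+	4430
OsYSL12	chr4	88620001	88624000	+	4432
OsYSL9	chr4	91700001	91704000	+	4586
OsYSL16	chr4	91780001	91784000	+	4590
OsOPT6	chr4	101620001	101624000	+	5082
OsYSL10	chr4	115660001	115664000	+	5784
OsOPT2	chr6	7060001	7064000	+	354
OsOPT3	chr6	7100001	7104000	+	356
OsOPT4	chr6	7380001	7384000	+	370
OsOPT5	chr8	46240001	46244000	+	2313
OsOPT9	chr8	76780001	76784000	+	3840
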