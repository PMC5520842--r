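block_id	id_a	chrom_a	start_a	end_a	id_b	chrom_b	start_b	end_b
block1	OsYSL2	chr2	86720001	86724000	OsYSL9	chr4	91700001	91704000
block1	OsYSL15	chr2	86800001	86804000	OsYSL16	chr4	91780001	91784000
block2	OsOPT8	chr2	93680001	93684000	OsOPT6	chr4	101620001	101624000
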