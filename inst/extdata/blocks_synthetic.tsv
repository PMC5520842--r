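block_id	chrom_a	start_a	end_a	chrom_b	start_b	end_b	n_anchors
block1	chr2	86720001	86804000	chr4	91700001	91784000	2
block2	chr2	93680001	93684000	chr4	101620001	101624000	1
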