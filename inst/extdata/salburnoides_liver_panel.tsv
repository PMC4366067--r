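gene	per_genome	sd_per_genome	per_cell_published	per_transcriptome	size_published
rpl8	0.8	0.1	1.1	1.5	0.8
eef1a	0.8	0.1	1.1	1.3	0.9
actb2	0.6	0.2	0.9	0.6	1.6
rpsa	0.9	0.3	1.3	1.5	0.9
pabpc1a	0.8	0.2	1.2	1.0	1.2
rpl35	0.8	0.2	1.2	1.5	0.8
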