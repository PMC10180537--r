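type	size	energy
hairpin	3	5.4
hairpin	4	5.6
hairpin	5	5.7
hairpin	6	5.4
hairpin	7	6.0
hairpin	8	5.5
hairpin	9	6.4
bulge	1	3.8
bulge	2	2.8
bulge	3	3.2
bulge	4	3.6
bulge	5	4.0
bulge	6	4.4
internal	2	1.5
internal	3	1.6
internal	4	1.7
internal	5	2.0
internal	6	2.1
multiloop_offset	0	3.4
multiloop_branch	0	0.4
multiloop_unpaired	0	0.1
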