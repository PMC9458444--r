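species	rrna	accession	length	shift
human	28S	NR_003287.4	5070	71
human	18S	NR_003286.4	1869	71
human	5.8S	NR_003285.3	157	71
human	5S	4V6X_A7	121	71
mouse	28S	NR_003279.1	4730	67
mouse	18S	NR_003278.3	1870	67
mouse	5.8S	NR_003280.2	157	67
mouse	5S	NR_030686.1	121	67
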