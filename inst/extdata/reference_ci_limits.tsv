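protein	replicate	fe_ci_lower	pv_ci_lower	fe_cutoff_published	pv_cutoff_published
RsmA	1	2.15	130	2.15	130
RsmA	2	2.33	135	2.15	130
RsmA	3	2.33	128	2.15	130
RsmE	1	4	180	4	170
RsmE	2	4.22	150	4	170
RsmE	3	4.62	181	4	170
RsmI	1	2.68	153	2.5	145
RsmI	3	2.53	137	2.5	145
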