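gene	name	role	sequence	start	end
gadR	gadR-FISA	SSP3_FISA	CGTAAACCTGCGTAAAAA	233	250
gadR	gadR-SSP1a	SSP1	GTCCATACCCTCATCTCCATT	38	57
gadR	gadR-SSP1b	SSP1	AATGTCCTTCGTTCTTGAT	19	37
gadR	gadR-SSP2	SSP2	AACTATCACCCCACAACGTCATCTC	194	218
gadR	gadR-SSP4	SSP4	ACCGTTCATAGGCGAAATTGTTTGT	372	396
gadC	gadC-FISA	SSP3_FISA	TGTTTTCTTCTTGCTCT	132	148
gadC	gadC-SSP1a	SSP1	ATGGTTATTCTCTGGGG	34	50
gadC	gadC-SSP1b	SSP1	TCTCTGGGGATTGATTG	42	58
gadC	gadC-SSP2	SSP2	TTGGGCGTTATAATTCCTGTTTTCTTCTTG	115	144
gadC	gadC-SSP4	SSP4	GGAGCGGTAGTGTGTTAGTTGGGTT	227	251
hyg	hyg-FISA	SSP3_FISA	GGACCGATGGCTGTGTA	321	337
hyg	hyg-SSP1a	SSP1	TGGTTGGCTTGTATGGA	83	99
hyg	hyg-SSP1b	SSP1	TCATTGACTGGAGCGAG	12	28
hyg	hyg-SSP2	SSP2	CGGGACTGTCGGGCGTACACAAATC	274	298
hyg	hyg-SSP4	SSP4	GACCGATGGCTGTGTAGAAGTACTC	322	346
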