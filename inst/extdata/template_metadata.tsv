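# Candidate template complexes: acetylcholine-binding-protein and chimeric
# alpha7 nAChR-LBD co-crystal structures, with percent sequence identity to
# the human alpha7 nAChR-LBD and crystallographic resolution. ki_nM is the
# reported alpha7 binding affinity of the co-crystallized ligand.
structure_id	ligand_id	protein	species	ki_nM	sequence_identity_pct	resolution_A
3SQ6	EPJ	a7-nrc	HS,LS	18	63.24	2.80
1UW6	NCT	AChBP	LS	170	24.75	2.20
3U8J	09O	AChBP	LS	136	23.88	2.35
3U8L	09Q	AChBP	LS	>10000	23.88	2.32
3U8M	09R	AChBP	LS	190	23.88	2.70
3U8K	09P	AChBP	LS	9970	23.88	2.47
3U8N	09S	AChBP	LS	847	23.88	2.35
2W8G	BS2	AChBP	AC	79.4	26.24	2.60
2W8F	BS1	AChBP	AC	79.4	26.24	2.70
2XYT	TC9	AChBP	AC	2975	26.24	2.05
2WN9	ZY5	AChBP	AC	235	25.24	1.75
2XYS	SY9	AChBP	AC	4854	26.24	1.91
2WNL	AN5	AChBP	AC	200	25.24	2.70
2WNL	AN4	AChBP	AC	200	25.24	2.70
2WNJ	ZY7	AChBP	AC	130	25.24	1.80
4AFT	QMR	AChBP	AC	322	26.24	3.2
4BQT	C5E	AChBP	AC	4200	26.24	2.88
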