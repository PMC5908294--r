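# Test-set XP docking scores: 12 compounds docked to the 2XYT-based and
# 3SQ6-based receptor conformations.
ligand_id	receptor_id	status	score
acetylcholine	2XYT	docked	-4.68
acetylcholine	3SQ6	docked	-4.812
epibatidine	2XYT	docked	-5.2
epibatidine	3SQ6	docked	-8.725
nicotine	2XYT	docked	-3.1
nicotine	3SQ6	docked	-7.512
cytisine	2XYT	docked	-3.65
cytisine	3SQ6	docked	-6.362
PNU282987	2XYT	docked	-4.518
PNU282987	3SQ6	docked	-5.878
mecamylamine	2XYT	docked	-3.564
mecamylamine	3SQ6	docked	-4.873
MG624	2XYT	docked	-4.954
MG624	3SQ6	failed	failed to dock
methyllycaconitine	2XYT	docked	-5.829
methyllycaconitine	3SQ6	failed	failed to dock
hexamethonium	2XYT	docked	-2.786
hexamethonium	3SQ6	docked	-1.001
NS1738	2XYT	docked	-7.108
NS1738	3SQ6	docked	-8.513
PNU120596	2XYT	docked	-4.992
PNU120596	3SQ6	docked	-6.188
SB206553	2XYT	docked	-4.373
SB206553	3SQ6	docked	-6.671
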