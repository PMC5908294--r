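# Training-set XP docking scores: 17 crystal ligands docked to the
# 3SQ6-based and 2XYT-based receptor conformations. "ND" = failed docking.
ligand_id	receptor_id	status	score
EPJ	3SQ6	docked	-8.725
EPJ	2XYT	docked	-5.2
ZY5	3SQ6	docked	-8.082
ZY5	2XYT	docked	-5.601
ZY7	3SQ6	docked	-8.047
ZY7	2XYT	docked	-5.537
09S	3SQ6	docked	-8.016
09S	2XYT	docked	-4.093
09Q	3SQ6	docked	-7.704
09Q	2XYT	docked	-5.072
AN5	3SQ6	docked	-7.673
AN5	2XYT	docked	-4.681
09R	3SQ6	docked	-7.666
09R	2XYT	docked	-5.109
NCT	3SQ6	docked	-7.512
NCT	2XYT	docked	-3.1
09O	3SQ6	docked	-7.439
09O	2XYT	docked	-3.656
QMR	3SQ6	docked	-7.353
QMR	2XYT	docked	-4.135
09P	3SQ6	docked	-7.257
09P	2XYT	docked	-3.616
AN4	3SQ6	docked	-6.982
AN4	2XYT	docked	-4.674
C5E	3SQ6	docked	-6.362
C5E	2XYT	docked	-3.65
TC9	3SQ6	failed	ND
TC9	2XYT	docked	-5.583
BS1	3SQ6	failed	ND
BS1	2XYT	docked	-5.015
BS2	3SQ6	failed	ND
BS2	2XYT	docked	-4.36
SY9	3SQ6	docked	-3.596
SY9	2XYT	docked	-4.218
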