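# Example pocket-definition file: the 41 residues lining the 1UW6 ligand
# binding pocket (author numbering). Chain assignment is illustrative (all
# "A"); adapt it to the chain layout of your own structure file. Pocket
# files for several structures are concatenated in one file; residue row
# order defines the atom correspondence used for superposition.
structure_id	chain_id	res_seq
1UW6	A	86
1UW6	A	88
1UW6	A	90
1UW6	A	140
1UW6	A	142
1UW6	A	143
1UW6	A	144
1UW6	A	145
1UW6	A	146
1UW6	A	147
1UW6	A	184
1UW6	A	185
1UW6	A	186
1UW6	A	187
1UW6	A	188
1UW6	A	189
1UW6	A	191
1UW6	A	192
1UW6	A	193
1UW6	A	194
1UW6	A	241
1UW6	A	243
1UW6	A	260
1UW6	A	261
1UW6	A	262
1UW6	A	263
1UW6	A	280
1UW6	A	282
1UW6	A	306
1UW6	A	307
1UW6	A	309
1UW6	A	310
1UW6	A	311
1UW6	A	312
1UW6	A	318
1UW6	A	319
1UW6	A	320
1UW6	A	321
1UW6	A	322
1UW6	A	323
1UW6	A	371
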