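species	is_tabaci	is_new	n_sequences	closest_accession	identity_min	identity_max
SSA1	TRUE	FALSE	19	AY903463	98.4	100.0
SSA2	TRUE	FALSE	4	AY057173	99.6	99.6
SSA6	TRUE	FALSE	5	AY903561	99.7	99.9
SSA9	TRUE	TRUE	3	AY903463	92.8	93.5
SSA10	TRUE	TRUE	11	FN821787	85.3	86.0
SSA11	TRUE	TRUE	3	FN821787	84.8	84.8
SSA12	TRUE	TRUE	18	JX993192	93.9	94.1
SSA13	TRUE	TRUE	2	EU760753	94.6	94.7
MEAM1	TRUE	FALSE	1	KC661294	99.9	99.9
MEAM2	TRUE	FALSE	7	AJ550177	97.1	97.1
MED	TRUE	FALSE	32	EU760732	96.5	99.9
IO	TRUE	FALSE	3	AY903538	99.1	99.7
B_Uganda1	FALSE	FALSE	13	AY903575	99.6	100.0
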