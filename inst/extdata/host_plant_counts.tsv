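host_plant	common_name	SSA1	SSA2	SSA6	SSA9	SSA10	SSA11	SSA12	SSA13	MEAM1	MEAM2	MED	IO	B_Uganda1	total_printed
Manihot esculenta	cassava	0	0	0	1	8	0	0	0	0	0	0	0	0	9
Pavonia urens	pavonia	1	1	3	1	0	3	0	0	1	5	12	0	1	27
Euphorbia heterophylla	milkweed	8	1	0	0	1	0	0	0	0	0	0	3	3	16
Cleome gynandra	spider plant	2	0	0	0	0	0	0	0	0	0	9	0	3	14
Vernonia amygdalina	bitter leaf	3	0	2	0	1	0	0	0	0	3	7	0	2	18
Commelina benghalensis	wandering jew	5	2	0	1	1	0	18	2	0	0	4	0	4	37
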