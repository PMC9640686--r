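rule_id	family	priority	required	forbidden
R001	TetR	1	PF00440	-
R002	SARP	2	PF03704,PF00486	-
R003	MarR	3	PF01047	-
R004	LacI	4	PF00356,PF13377	-
R005	MerR	5	PF13411	PF00440
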