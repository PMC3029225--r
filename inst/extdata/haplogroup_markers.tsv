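variant	haplogroup
663A>G	A
827A>G	B4
1119T>C	B4
709G>A	B5
1598G>A	B5
1382A>C	D4
681T>C	D5
752C>T	D5
1048C>T	D5
1107T>C	D5
1005T>C	F2
1041A>G	M9a
1541T>C	R5b
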