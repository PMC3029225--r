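position	ref	alt	kind	name	ci_percent	wc_arrow	wc_pair	previously_reported	case_count	control_count
663	A	G	substitution	663A>G	78.6	down	A-U	yes	15	5
681	T	C	substitution	681T>C	85.7	down	U-A	yes	5	8
709	G	A	substitution	709G>A	64.3	down	G-C	yes	90	102
723	A	G	substitution	723A>G	28.6	.	.	yes	2	2
735	A	G	substitution	735A>G	78.6	.	.	yes	2	5
747	A	G	substitution	747A>G	100	down	A-U	no	1	0
752	C	T	substitution	752C>T	100	.	.	yes	26	17
789	T	C	substitution	789T>C	85.7	.	.	yes	1	1
813	A	G	substitution	813A>G	28.6	.	.	yes	1	0
827	A	G	substitution	827A>G	92.9	.	.	yes	16	12
839	A	G	substitution	839A>G	78.6	down	A-U	yes	1	0
929	A	T	substitution	929A>T	42.9	down	A-U	no	1	0
942	A	G	substitution	942A>G	64.3	.	.	yes	1	0
951	G	A	substitution	951G>A	92.9	down	G-C	yes	2	2
953	T	C	substitution	953T>C	57.1	.	.	yes	1	0
961	.	C	insertion	961insC	42.9	.	.	yes	9	14
961	T	C	substitution	961T>C	42.9	.	.	yes	2	4
980	T	C	substitution	980T>C	64.3	down	U-A	yes	3	0
990	T	C	substitution	990T>C	71.4	down	U-A	yes	1	0
1005	T	C	substitution	1005T>C	35.7	.	.	yes	21	22
1009	C	T	substitution	1009C>T	21.4	.	.	yes	6	8
1027	A	G	substitution	1027A>G	92.9	.	.	yes	1	0
1041	A	G	substitution	1041A>G	42.9	.	.	yes	2	4
1048	C	T	substitution	1048C>T	57.1	.	.	yes	10	11
1095	T	C	substitution	1095T>C	92.9	down	U-A	yes	4	1
1107	T	C	substitution	1107T>C	85.7	.	.	yes	36	25
1119	T	C	substitution	1119T>C	50.0	.	.	yes	13	17
1187	T	C	substitution	1187T>C	57.1	.	.	yes	1	0
1282	G	A	substitution	1282G>A	71.4	.	.	yes	1	0
1310	C	T	substitution	1310C>T	85.7	down	G-C	yes	1	0
1382	A	C	substitution	1382A>C	92.9	down	A-U	yes	14	9
1391	T	C	substitution	1391T>C	64.3	.	.	yes	1	1
1393	G	A	substitution	1393G>A	28.6	up	A-U	yes	2	0
1413	T	C	substitution	1413T>C	78.6	up	C-G	yes	1	0
1442	G	A	substitution	1442G>A	42.9	.	.	yes	1	0
1462	G	A	substitution	1462G>A	50.0	.	.	yes	1	0
1494	C	T	substitution	1494C>T	78.6	up	U-A	yes	2	0
1503	G	A	substitution	1503G>A	50.0	up	A-U	yes	1	0
1541	T	C	substitution	1541T>C	78.6	.	.	yes	6	4
1555	A	G	substitution	1555A>G	85.7	up	A-U	yes	33	0
1598	G	A	substitution	1598G>A	50.0	.	.	yes	12	9
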