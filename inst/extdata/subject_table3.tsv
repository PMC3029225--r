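variant	gjb2	subject_id	sex	configuration	onset_age_years	pta_right_db	pta_left_db	drug_use	severity
1555A>G	polymorphism	FE003-IV-1	M	Slope	1	98	98	yes	profound
1555A>G	polymorphism	FE007-IV-6	M	Slope	2	100	100	yes	profound
1555A>G	polymorphism	FE008-III-7	F	Slope	10	58	78	no	severe
1555A>G	polymorphism	FE0128-IV-1	F	Slope	2	102	98	yes	profound
1555A>G	polymorphism	FE019-IV-1	F	Slope	2	67	82	yes	severe
1555A>G	polymorphism	FE020-III-15	M	Slope	8	81	74	yes	severe
1555A>G	polymorphism	FE036-III-1	M	Slope	10	58	49	no	moderate
1555A>G	polymorphism	FE081-III-1	M	Slope	16	50	56	yes	moderate
1555A>G	polymorphism	FE122-III-2	F	Slope	2	71	53	yes	moderate
1555A>G	polymorphism	FE141-III-1	F	Slope	2	24	30	no	mild
1555A>G	polymorphism	FE154-III-1	F	Slope	18	61	60	no	moderate
1555A>G	polymorphism	FE160-III-1	F	Slope	5	61	74	no	severe
1555A>G	polymorphism	FE163-III-3	M	Flat	2	110	99	yes	profound
1555A>G	polymorphism	FE300-II-12	F	Slope	3	110	105	yes	profound
1555A>G	polymorphism	FE304-II-2	F	Slope	3	100	80	yes	profound
1555A>G	polymorphism	FE317-III-10	M	Slope	4	94	93	yes	profound
1555A>G	polymorphism	FE350-III-1	F	Flat	1	100	100	yes	profound
1555A>G	polymorphism	NB038-III-1	M	Flat	1	90	87	yes	profound
1555A>G	polymorphism	NB048-III-2	F	Slope	1	78	81	no	severe
1555A>G	polymorphism	NB052-III-2	F	Flat	1	120	102	no	profound
1555A>G	polymorphism	NB076-III-1	M	Flat	1	118	118	yes	profound
1555A>G	polymorphism	NB078-III-2	F	Flat	6	110	117	yes	profound
1555A>G	polymorphism	NB079-III-1	M	Flat	1	102	102	yes	profound
1555A>G	polymorphism	NB094-III-2	F	Flat	1	117	117	yes	profound
1555A>G	polymorphism	NB111-III-2	F	Slope	3	83	86	yes	severe
1555A>G	polymorphism	NB126-III-2	F	Slope	2	84	92	no	profound
1555A>G	polymorphism	NB137-III-1	F	Slope	2	111	115	no	profound
1555A>G	polymorphism	ZX019-II-2	F	Slope	5	59	62	yes	moderate
1555A>G	polymorphism	ZX022-III-3	M	Flat	2	101	102	yes	profound
1555A>G	polymorphism	ZX025-III-14	M	Flat	1	113	108	yes	profound
1555A>G	polymorphism	ZX028-IV-1	F	Slope	3	87	87	no	severe
1555A>G	polymorphism	ZX037-II-7	M	Flat	5	30	27	no	mild
1555A>G	polymorphism	ZX047-III-1	M	Slope	6	78	79	no	severe
1494C>T	polymorphism	FE247-III-1	M	Flat	3	100	100	yes	profound
1494C>T	polymorphism	NB133-II-1	M	Slope	2	86	88	yes	severe
1095T>C	polymorphism	FE312	F	Slope	9	82	80	yes	severe
1095T>C	polymorphism	NB021	M	Slope	10	36	37	no	mild
1095T>C	polymorphism	NB067	M	Flat	1	93	93	no	profound
1095T>C	polymorphism	NB100	F	Flat	5	100	95	yes	profound
747A>G	polymorphism	NS016-III-4	M	Flat	1	100	80	yes	profound
839A>G	polymorphism	NB005-III-1	F	Flat	1	78	81	yes	severe
1027A>G	polymorphism	FE239-II-1	M	Slope	18	82	85	no	severe
1310C>T	polymorphism	NS071-IV-1	M	Flat	1	91	92	no	profound
1413T>C	235DelC/299DelAT	ZX039-IV-1	F	Flat	1	114	111	no	profound
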