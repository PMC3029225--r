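pos5	pos3	wild_paired
663	700	yes
681	696	yes
692	709	yes
747	772	yes
839	858	yes
916	929	yes
938	951	yes
968	980	yes
990	999	yes
1080	1095	yes
1310	1330	yes
1368	1382	yes
1393	1436	no
1413	1422	no
1494	1555	no
1503	1516	no
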