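case_id	risk	derivation	mutation	reported_group
1	NA	Recurrence	E11: p.K550_K558del	A
2	High	Primary	E11: p.W557_K558del	A
3	High	Primary	E11: p.W557_K558delinsE	A
4	High	Primary	E11: p.W557_V559delinsF	A
5	High	Primary	E11: p.W557_P573delinsS	A
6	High	Primary	E11: p.K550_K558del	A
7	High	Primary	E11: p.E554_V560delinsV	A
8	High	Primary	E11: p.W557_V559delinsF, E13: p.V654A	A
9	High	Primary	E11: p.W557_E561del	A
10	High	Primary	E11: p.W557_K558del	A
11	High	Primary	E11: p.P551_K558delinsQ	A
12	High	Primary	E11: p.W557_V560delinsF	A
13	NA	Metastasis	E11: p.Y570_L576del	B
14	High	Primary	E11: p.L576P	B
15	High	Primary	E11: p.V559G	B
16	High	Primary	E11: p.V560D	B
17	NA	Metastasis	E11: p.K558_T574del	B
18	High	Primary	E11: p.V560D	B
19	Low	Primary	E11: p.W557_E562del	C
20	Low	Primary	E11: p.K550_V555delinsL	C
21	Low	Primary	E11: p.W557_K558del	C
22	Intermediate	Primary	E11: p.W557_K558del	C
23	Low	Primary	E11: p.W557_K558del	C
24	Intermediate	Primary	E11: p.W557_V559delinsC	C
25	Low	Primary	E11: p.W557R	D
26	Low	Primary	E11: p.V559D	D
27	Low	Primary	E11: p.D579del	D
28	Low	Primary	E11: p.K558_E562del	D
29	Low	Primary	E11: p.K558_E562del	D
30	Low	Primary	E11: p.D579del	D
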