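category	SBSS1	SBSS2	SBSS3	SBSS4	SBSS5
A[C>A]A	3.94475e-06	0.000306049	3.62882e-12	0.000235474	1.26335e-07
A[C>A]C	0.117351	1.41946e-14	4.06586e-06	7.01837e-07	0.0833579
A[C>A]G	2.7677e-07	0.00177228	0.24359	6.04929e-06	0.113563
A[C>A]T	8.02729e-05	1.28768e-11	2.04724e-06	2.2282e-05	2.7757e-06
C[C>A]A	0.000121018	2.7919e-08	0.00233096	0.0660729	0.000252867
C[C>A]C	0.000358225	0.000192857	0.00201514	0.000361559	1.96727e-06
C[C>A]G	0.000766458	3.52694e-09	6.47376e-08	1.8657e-08	0.000401891
C[C>A]T	0.000267784	2.00032e-08	4.00421e-11	9.82069e-07	0.0928332
G[C>A]A	6.4254e-11	0.000731514	1.30561e-06	2.8489e-07	0.000116782
G[C>A]C	7.09435e-06	4.78035e-05	8.80783e-10	1.19876e-05	0.118523
G[C>A]G	9.30753e-06	0.000279648	1.51441e-08	3.24559e-07	1.96394e-11
G[C>A]T	5.8168e-08	0.000260964	2.8409e-06	0.000115844	4.70214e-05
T[C>A]A	3.82463e-05	0.157709	1.41791e-06	2.07157e-05	5.35164e-06
T[C>A]C	1.42942e-14	9.27656e-06	6.2213e-05	0.0041172	0.00161713
T[C>A]G	0.000462991	7.85399e-06	7.44255e-10	3.73359e-11	0.000321753
T[C>A]T	0.315686	7.27559e-05	2.73066e-24	0.175198	0.00046653
A[C>G]A	0.0718908	0.000244946	3.81136e-09	0.00136896	0.00156866
A[C>G]C	0.000218753	0.000143132	2.65782e-05	3.02912e-08	1.2944e-09
A[C>G]G	1.45116e-05	0.114033	6.86386e-06	4.11678e-08	0.000364296
A[C>G]T	0.000243536	0.000269094	9.39744e-05	1.40687e-08	0.000137316
C[C>G]A	0.000730773	8.56298e-09	0.000375662	0.000410872	1.23144e-14
C[C>G]C	1.04781e-06	1.74865e-10	0.128056	8.11693e-13	9.98958e-05
C[C>G]G	0.000916897	9.6211e-08	0.000256031	2.63273e-09	2.27713e-07
C[C>G]T	5.91057e-07	0.00123328	5.80942e-05	0.00137033	0.00226616
G[C>G]A	1.37397e-07	1.54365e-05	2.41081e-07	0.00229424	0.00017587
G[C>G]C	0.00248893	0.000109589	1.03241e-05	9.71042e-05	0.00480826
G[C>G]G	0.000527877	9.44075e-08	0.000180358	2.27956e-08	2.60184e-07
G[C>G]T	0.10634	6.25236e-06	0.000701911	0.000323649	1.81307e-07
T[C>G]A	0.0408779	1.53464e-05	9.90635e-08	9.39918e-09	2.5119e-07
T[C>G]C	0.127533	0.00078044	9.9402e-08	5.42355e-05	2.00062e-06
T[C>G]G	7.55683e-15	1.23488e-05	0.0010223	0.170129	1.31607e-07
T[C>G]T	3.46547e-08	6.26262e-06	4.02161e-06	2.06964e-05	6.15555e-06
A[C>T]A	1.71631e-07	6.49544e-05	6.89456e-05	4.27083e-06	6.42227e-12
A[C>T]C	2.61377e-11	6.71017e-10	1.05512e-08	0.00201844	0.165321
A[C>T]G	3.77176e-14	1.47953e-07	1.92174e-07	5.42708e-11	0.0537787
A[C>T]T	2.13252e-06	6.31964e-07	1.31447e-07	0.128863	6.37532e-05
C[C>T]A	8.52079e-13	0.0896772	2.81222e-06	0.000440538	6.97065e-07
C[C>T]C	0.00674331	0.000283086	4.99462e-15	5.58265e-16	1.25444e-05
C[C>T]G	1.33867e-12	6.17962e-06	2.14286e-13	0.000844659	0.000262387
C[C>T]T	3.23796e-05	1.07994e-05	0.000136305	3.52378e-06	3.36738e-06
G[C>T]A	0.000110199	2.08315e-06	3.95456e-05	3.15687e-07	0.000116352
G[C>T]C	5.80365e-09	0.00031023	5.02822e-08	0.0882407	5.7723e-05
G[C>T]G	5.34286e-05	1.38786e-06	8.37037e-05	9.38777e-05	1.75425e-05
G[C>T]T	1.99093e-05	0.000155611	2.02939e-06	1.42527e-05	1.0746e-06
T[C>T]A	3.58908e-10	8.2895e-07	6.57629e-08	6.05667e-07	0.000589435
T[C>T]C	3.68929e-06	8.23637e-06	9.46504e-19	8.62528e-05	8.33451e-07
T[C>T]G	2.06251e-05	7.46246e-07	7.20347e-05	3.46661e-08	1.95879e-09
T[C>T]T	0.00118255	6.10244e-15	0.000672062	2.65715e-07	2.83558e-20
A[T>A]A	1.8441e-05	9.01612e-05	2.43076e-11	4.37354e-12	6.09914e-06
A[T>A]C	5.08571e-13	2.00514e-05	3.58315e-11	1.70409e-07	0.000287757
A[T>A]G	0.000116989	3.01368e-07	0.164609	0.000142753	7.57022e-08
A[T>A]T	5.66085e-05	3.0632e-05	6.71513e-05	2.83542e-07	1.2563e-10
C[T>A]A	2.14027e-05	8.1347e-08	1.09598e-05	0.00019135	1.11113e-05
C[T>A]C	1.0356e-06	3.13904e-06	0.000925472	0.00183448	0.000864774
C[T>A]G	0.000395211	0.000588935	1.638e-07	0.000609604	9.84118e-07
C[T>A]T	0.000767026	0.0834791	1.59062e-09	3.30334e-05	8.47388e-05
G[T>A]A	0.000469525	1.82708e-09	5.16116e-09	0.000431931	5.99621e-05
G[T>A]C	1.87671e-07	9.31094e-09	0.000331116	0.000265117	7.22001e-07
G[T>A]G	1.0043e-07	1.79131e-05	0.000101218	8.82095e-12	5.10439e-07
G[T>A]T	1.70503e-06	0.000601678	6.61851e-05	0.000477211	3.7847e-08
T[T>A]A	0.0673183	8.87229e-09	9.92208e-09	4.06006e-06	2.25938e-09
T[T>A]C	0.000242972	0.0648324	1.21813e-07	1.50998e-06	1.43632e-06
T[T>A]G	0.000101342	5.08651e-06	0.0590107	4.70624e-08	2.26068e-05
T[T>A]T	5.48544e-07	0.233418	5.52611e-05	0.000290865	5.10653e-06
A[T>C]A	0.0012188	6.03319e-07	3.30749e-06	0.000969928	5.49238e-10
A[T>C]C	0.127052	0.000553799	2.26885e-06	0.000758526	1.30519e-06
A[T>C]G	4.42987e-05	7.29282e-05	3.8038e-05	9.89706e-07	1.31903e-09
A[T>C]T	4.39801e-05	1.45027e-05	5.18598e-06	0.000735182	0.00156719
C[T>C]A	2.52698e-05	4.94732e-11	1.16316e-06	3.34338e-05	2.2755e-07
C[T>C]C	3.91419e-08	4.34463e-05	1.21608e-09	3.77969e-10	0.000851804
C[T>C]G	0.000723589	0.000164267	6.35086e-05	2.75765e-11	1.36007e-05
C[T>C]T	3.75387e-05	6.83361e-05	1.69137e-06	0.000270831	5.1608e-11
G[T>C]A	0.000167618	7.74264e-09	0.000362902	7.01045e-05	3.1739e-06
G[T>C]C	7.3571e-06	1.79096e-05	3.3584e-06	1.08484e-05	0.000243737
G[T>C]G	1.11636e-05	1.64779e-11	0.000130634	3.20794e-15	0.000113699
G[T>C]T	0.00101718	2.7414e-15	0.000103233	5.20769e-05	0.0421821
T[T>C]A	1.73658e-05	5.81471e-11	0.00157418	3.0234e-06	0.00175727
T[T>C]C	4.2906e-08	5.11522e-06	0.110517	1.98145e-06	6.13601e-11
T[T>C]G	6.09838e-07	5.62195e-10	3.8186e-06	0.0384385	6.01541e-08
T[T>C]T	0.000772749	4.14069e-06	1.63199e-09	1.32472e-06	0.000148308
A[T>G]A	0.000127036	0.19877	9.46939e-08	0.00230969	0.000151424
A[T>G]C	1.57952e-07	6.03416e-06	1.2738e-07	9.27955e-05	5.32403e-07
A[T>G]G	5.71137e-07	0.000587412	6.90637e-14	2.44925e-05	3.17764e-12
A[T>G]T	0.000187506	1.11597e-05	3.63223e-07	0.000262735	7.36961e-05
C[T>G]A	0.000428718	1.15596e-05	3.51075e-10	5.51747e-08	2.42866e-05
C[T>G]C	0.000155081	4.96173e-09	0.000154328	0.000256804	0.000851437
C[T>G]G	2.52853e-05	0.0465017	0.000510515	0.000259836	0.000369882
C[T>G]T	2.58423e-10	4.94519e-08	8.34524e-05	0.000105392	0.301744
G[T>G]A	1.14451e-09	0.00118787	4.0115e-06	2.21411e-06	3.56382e-08
G[T>G]C	7.71788e-17	2.13459e-05	0.191378	7.26062e-05	0.000853436
G[T>G]G	9.22986e-07	1.71863e-08	1.07249e-06	0.00311404	0.000709608
G[T>G]T	0.000273295	7.61555e-10	9.54397e-07	0.000104185	1.87566e-06
T[T>G]A	1.28e-06	1.7685e-06	0.0762964	0.141764	0.000460704
T[T>G]C	0.00131041	8.57362e-05	0.000173018	9.01392e-06	0.0053434
T[T>G]G	1.66785e-05	1.06275e-06	4.45093e-09	0.163148	2.12846e-05
T[T>G]T	0.00171589	2.5607e-12	0.0135288	2.62496e-06	1.84328e-08
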