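category	IDS1	IDS2	IDS3
1:Del:C:0	0.000106563	5.56671e-14	0.105162
1:Del:C:1	3.38986e-06	2.93888e-05	0.136036
1:Del:C:2	0.000125365	2.88891e-09	0.0909103
1:Del:C:3	2.88869e-12	7.52558e-06	0.0014242
1:Del:C:4	5.75231e-10	0.000231889	0.000431411
1:Del:C:5	1.82419e-05	6.86812e-15	0.000217212
1:Del:T:0	9.83314e-05	0.00158326	0.0547388
1:Del:T:1	1.9262e-16	5.18477e-05	2.37307e-06
1:Del:T:2	6.98332e-05	0.000134185	2.70723e-06
1:Del:T:3	0.000126772	0.000502254	5.13417e-10
1:Del:T:4	0.000293815	0.00412107	6.54902e-10
1:Del:T:5	3.10346e-05	0.00176291	2.53306e-06
1:Ins:C:0	1.0818e-05	7.0041e-06	6.3202e-07
1:Ins:C:1	4.79367e-06	6.20999e-05	3.57886e-10
1:Ins:C:2	1.756e-08	3.93435e-05	4.53061e-09
1:Ins:C:3	9.75358e-10	1.6448e-15	2.7379e-05
1:Ins:C:4	1.78294e-05	0.200232	1.51645e-08
1:Ins:C:5	4.44747e-05	0.00301258	3.94515e-09
1:Ins:T:0	4.29596e-06	0.000315804	9.05412e-07
1:Ins:T:1	4.6907e-06	0.000204611	4.90634e-07
1:Ins:T:2	4.68063e-05	5.42613e-07	5.41938e-05
1:Ins:T:3	3.81229e-07	4.6738e-13	0.121448
1:Ins:T:4	0.054695	1.30151e-10	0.000100949
1:Ins:T:5	0.122804	0.221457	2.50952e-12
2:Del:R:0	0.000976572	0.000281957	0.000133563
2:Del:R:1	6.95677e-05	7.97005e-05	1.00277e-07
2:Del:R:2	1.15005e-06	3.99526e-06	6.24793e-05
2:Del:R:3	0.000173186	0.000621749	5.07076e-10
2:Del:R:4	2.9559e-07	0.00149767	1.52566e-07
2:Del:R:5	1.54683e-07	0.00121754	0.000608397
3:Del:R:0	0.000218224	3.35232e-09	1.01007e-14
3:Del:R:1	0.000476794	0.000222136	3.22426e-11
3:Del:R:2	4.19767e-05	0.0043168	1.02258e-09
3:Del:R:3	0.00248272	1.07564e-05	4.63304e-06
3:Del:R:4	0.0735623	2.61834e-07	2.37963e-05
3:Del:R:5	0.000100186	1.86523e-08	1.43165e-09
4:Del:R:0	1.67278e-07	3.02392e-05	3.88141e-05
4:Del:R:1	5.42756e-05	5.11692e-06	8.19921e-07
4:Del:R:2	1.48641e-10	3.98788e-13	1.27929e-05
4:Del:R:3	0.000370495	0.00130007	1.03396e-11
4:Del:R:4	1.4341e-05	0.00161688	6.84297e-16
4:Del:R:5	1.68255e-05	4.8265e-05	1.59743e-09
5:Del:R:0	1.47574e-07	0.00024906	3.62855e-07
5:Del:R:1	1.26238e-06	0.000670126	0.00604795
5:Del:R:2	8.87559e-05	0.000294627	2.25233e-05
5:Del:R:3	0.00164126	3.10326e-05	2.50347e-07
5:Del:R:4	2.07449e-07	3.94592e-11	9.92762e-06
5:Del:R:5	0.0032437	3.48633e-05	0.000884685
2:Ins:R:0	3.57274e-10	9.64711e-05	1.48808e-08
2:Ins:R:1	5.53769e-07	0.000177402	6.70544e-05
2:Ins:R:2	0.0797385	0.000567376	1.94394e-05
2:Ins:R:3	3.76713e-05	7.06221e-05	0.000341965
2:Ins:R:4	8.4841e-08	0.110868	3.9461e-10
2:Ins:R:5	0.000416676	1.74209e-08	0.000800189
3:Ins:R:0	3.81411e-11	1.44651e-12	0.0996813
3:Ins:R:1	2.22708e-05	4.20017e-07	1.17815e-09
3:Ins:R:2	2.87562e-06	0.000400584	8.79976e-11
3:Ins:R:3	0.00203728	6.65592e-09	0.00513162
3:Ins:R:4	2.57722e-10	1.98358e-07	0.00139253
3:Ins:R:5	0.000362629	0.00437799	1.16336e-05
4:Ins:R:0	0.000530743	5.03034e-06	6.48089e-05
4:Ins:R:1	0.188036	7.95979e-05	4.52774e-06
4:Ins:R:2	6.77398e-06	0.000541516	0.000111804
4:Ins:R:3	0.000407913	0.199034	1.82674e-11
4:Ins:R:4	2.29342e-13	0.000229353	0.000744326
4:Ins:R:5	8.74296e-05	2.441e-06	7.00222e-07
5:Ins:R:0	0.00384283	0.0757435	8.41554e-20
5:Ins:R:1	0.000164957	0.000121382	7.08061e-10
5:Ins:R:2	0.0016877	3.37742e-07	0.00407878
5:Ins:R:3	9.14845e-05	0.000263104	0.0228459
5:Ins:R:4	0.0935405	2.36688e-06	1.24071e-05
5:Ins:R:5	0.269375	0.000239488	7.5041e-05
2:Del:M:1	8.44661e-08	7.96381e-05	0.339369
3:Del:M:1	0.000128471	0.00102399	1.04712e-09
3:Del:M:2	5.90448e-13	3.13358e-09	0.00255508
4:Del:M:1	3.49415e-07	0.000152123	0.00341782
4:Del:M:2	0.000215157	6.57319e-08	0.000129667
4:Del:M:3	0.00017665	7.6397e-07	0.000214332
5:Del:M:1	4.88476e-08	0.0760608	4.05226e-07
5:Del:M:2	8.40449e-08	0.0834808	8.57855e-09
5:Del:M:3	8.04439e-07	1.97009e-05	1.26693e-05
5:Del:M:4	0.0970473	3.70157e-06	7.91062e-16
5:Del:M:5	1.21213e-18	6.88049e-05	0.000505833
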