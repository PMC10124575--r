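category	CNS1	CNS2	CNS3
0:homdel:0-100kb	0.000210948	0.00120943	4.70382e-05
0:homdel:100kb-1Mb	1.03729e-20	1.61132e-12	3.156e-16
0:homdel:>1Mb	0.199725	1.92274e-09	6.49016e-07
1:LOH:0-100kb	2.52935e-05	7.5039e-11	0.0145736
1:LOH:100kb-1Mb	0.00103113	0.000102514	3.2327e-06
1:LOH:1Mb-10Mb	6.34297e-05	2.69416e-06	1.9236e-05
1:LOH:10Mb-40Mb	3.67933e-05	9.70113e-08	0.000614253
1:LOH:>40Mb	0.00171117	0.173301	0.383761
2:LOH:0-100kb	0.0712082	0.000256873	1.44482e-07
2:LOH:100kb-1Mb	2.5731e-06	1.34165e-06	4.5737e-09
2:LOH:1Mb-10Mb	1.44101e-07	4.44144e-07	0.000263871
2:LOH:10Mb-40Mb	4.21637e-05	5.2593e-07	1.70953e-12
2:LOH:>40Mb	1.23033e-05	1.55687e-07	1.11534e-05
3-4:LOH:0-100kb	7.94098e-08	6.33288e-07	2.04394e-05
3-4:LOH:100kb-1Mb	0.000329637	0.000147336	7.55816e-07
3-4:LOH:1Mb-10Mb	0.00159581	1.38927e-10	0.00293918
3-4:LOH:10Mb-40Mb	0.243943	0.138119	0.0509553
3-4:LOH:>40Mb	0.000466045	0.000627599	1.12873e-10
5-8:LOH:0-100kb	2.37505e-11	0.121756	0.000769665
5-8:LOH:100kb-1Mb	0.000744902	5.15917e-07	0.000216528
5-8:LOH:1Mb-10Mb	1.6352e-08	3.11809e-07	0.000400371
5-8:LOH:10Mb-40Mb	8.55614e-06	0.000765316	3.47192e-05
5-8:LOH:>40Mb	2.16754e-05	1.76923e-06	5.77889e-05
9+:LOH:0-100kb	0.0299313	8.71882e-05	0.00464502
9+:LOH:100kb-1Mb	9.67008e-05	7.35163e-06	0.1014
9+:LOH:1Mb-10Mb	9.9752e-05	0.000326587	0.000248593
9+:LOH:10Mb-40Mb	1.25868e-09	4.80724e-06	3.5371e-11
9+:LOH:>40Mb	0.387483	0.0015783	2.66255e-05
2:het:0-100kb	0.00217808	0.227545	0.000385122
2:het:100kb-1Mb	0.00013559	0.000231532	0.00126818
2:het:1Mb-10Mb	2.39529e-09	3.04706e-05	7.87152e-07
2:het:10Mb-40Mb	1.60843e-05	9.17514e-09	8.12086e-05
2:het:>40Mb	0.058055	3.94604e-13	0.367056
3-4:het:0-100kb	3.04495e-14	0.0154149	1.11851e-07
3-4:het:100kb-1Mb	8.88491e-05	0.000378809	7.78627e-12
3-4:het:1Mb-10Mb	4.57794e-06	6.04595e-05	1.45478e-06
3-4:het:10Mb-40Mb	7.66269e-05	2.36429e-05	0.000340613
3-4:het:>40Mb	2.15357e-07	0.000608192	0.000133137
5-8:het:0-100kb	5.33654e-16	0.000597007	9.9352e-11
5-8:het:100kb-1Mb	0.00010359	1.08198e-05	2.44653e-05
5-8:het:1Mb-10Mb	9.44995e-11	4.07674e-05	7.75559e-07
5-8:het:10Mb-40Mb	1.70598e-07	3.20261e-12	2.26384e-06
5-8:het:>40Mb	2.03248e-06	1.04929e-13	0.000125907
9+:het:0-100kb	3.05347e-05	4.27336e-08	4.68125e-10
9+:het:100kb-1Mb	0.000493399	1.4687e-05	4.16776e-06
9+:het:1Mb-10Mb	3.63498e-06	0.316285	3.70944e-06
9+:het:10Mb-40Mb	3.50561e-12	0.000460574	7.77016e-05
9+:het:>40Mb	2.31128e-05	4.42449e-07	0.0694855
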