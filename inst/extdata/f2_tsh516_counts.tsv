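marker	chrom	pos	n_a	n_h	n_b
mSI_26	CH1	3377732	5	228	118
mSI_88	CH1	3499444	5	224	111
mSI_89	CH1	3525756	5	233	114
mSI_32	CH1	3649333	4	236	120
mTcCIR15	CH1	3711664	4	227	117
mSI_73	CH1	3790637	4	291	138
mSI_101	CH1	3935902	3	243	119
mSI_102	CH1	3966163	2	249	119
mSI_140	CH1	3988656	2	217	125
mSI_141	CH1	4010921	2	308	138
mSI_103	CH1	4021267	3	387	228
mSI_366	CH1	4053385	0	508	253
mSI_367	CH1	4054418	0	366	216
mSI_369	CH1	4057532	0	419	221
mSI_440	CH1	4066036	0	476	253
mSI_370	CH1	4070474	0	466	266
mSI_372	CH1	4073585	0	297	170
mSI_375	CH1	4091577	2	429	228
mSI_107	CH1	4130575	4	374	212
mTcCIR356	CH1	4149062	6	232	118
mSI_112	CH1	4233257	6	339	163
mSI_113	CH1	4252975	6	284	172
mSI_462	CH4	1414	222	425	2
mSI_466	CH4	4737	191	385	0
mSI_474	CH4	10127	198	380	0
mSI_7	CH4	20673	259	488	0
mSI_34	CH4	28166	238	487	0
mSI_8	CH4	28166	142	270	0
mTcCir312	CH4	32259	277	516	0
mSI_35	CH4	33618	183	348	0
mSI_2	CH4	43494	191	335	0
mSI_542	CH4	63388	33	68	0
mSI_303	CH4	119995	299	578	0
mSI_458	CH4	136890	208	399	0
mSI_460	CH4	139590	198	406	0
mSI_308	CH4	139780	211	408	0
mSI_309	CH4	141679	205	411	0
mSI_310	CH4	142517	193	383	0
mSI_315	CH4	233706	301	563	0
mSI_402	CH4	246098	259	506	0
mSI_535	CH4	252815	110	232	0
mSI_411	CH4	258684	125	242	1
mS_413	CH4	270916	118	253	1
mSI_39	CH4	278179	277	421	1
mSI_42	CH4	343424	109	233	2
mSI_46	CH4	428250	119	230	2
mSI_54	CH4	751986	55	127	4
mSI_294	CH4	1686245	109	248	16
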