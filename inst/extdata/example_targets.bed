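1	2108412	2110412
1	2628571	2630571
1	2782209	2784209
1	4249388	4251388
1	4502074	4504074
1	4633984	4635984
1	4998362	5000362
1	5432794	5434794
1	7081648	7083648
1	7328795	7330795
1	7768559	7770559
1	7776721	7778721
1	7870537	7872537
1	8075258	8077258
1	8228366	8230366
1	8286468	8288468
1	8432390	8434390
1	9086472	9088472
1	9201916	9203916
1	9683741	9685741
1	11284321	11286321
1	13134740	13136740
1	14183192	14185192
1	16157106	16159106
1	17757852	17759852
1	17759858	17761858
1	18120554	18122554
1	18433265	18435265
1	18457743	18459743
1	18774630	18776630
1	19255358	19257358
1	19922465	19924465
1	21386862	21388862
1	21586412	21588412
1	22222940	22224940
1	22830978	22832978
1	23190885	23192885
1	23254835	23256835
1	23651644	23653644
1	24733735	24735735
1	25131444	25133444
1	26337302	26339302
1	26365677	26367677
1	26709043	26711043
1	27375563	27377563
1	28392192	28394192
1	28461866	28463866
1	28543065	28545065
1	29041831	29043831
1	29499896	29501896
1	29686156	29688156
1	29946214	29948214
1	30600548	30603324
1	30863038	30865038
1	31371315	31373315
1	32079584	32081584
1	32293434	32295434
1	32705509	32707509
1	32776613	32778613
1	33420421	33422421
1	35267313	35269313
1	35288617	35290617
1	35527075	35529075
1	35735317	35737317
1	35934208	35936208
1	36451989	36453989
1	37213263	37215263
1	37474280	37476280
1	37762560	37764560
1	38466576	38468576
1	40260427	40262427
1	41128976	41130976
1	42187189	42189189
1	43991566	43993566
1	44125917	44127917
1	44246985	44248985
1	44492929	44494929
1	46803862	46805862
1	46945854	46947854
1	47044326	47046326
1	47171569	47173569
1	47456293	47458293
1	47719600	47721600
1	47790466	47792466
1	49184987	49186987
1	49669937	49671937
1	49863328	49865328
1	50211346	50213346
1	51441364	51443364
1	52254490	52256490
1	53089211	53091211
1	53398656	53400656
1	53553756	53557447
1	54462342	54464342
1	54536640	54538640
1	55006136	55008136
1	55064143	55066143
1	55149510	55151510
1	55335071	55337071
1	55778211	55780211
1	57002749	57004749
1	57252222	57254222
1	57815036	57817036
1	58241367	58243367
1	59072243	59074243
1	59788604	59790604
2	982457	984457
2	1188113	1190113
2	2007022	2009022
2	2240893	2242893
2	2578185	2580185
2	5592547	5594547
2	5632045	5634045
2	6479364	6481364
2	6841049	6843049
2	6848185	6850185
2	7531973	7533973
2	7606358	7608358
2	7614773	7616773
2	8297093	8299093
2	8591402	8593402
2	9202457	9204457
2	9476425	9478425
2	9764985	9766985
2	10685984	10687984
2	11561555	11563555
2	11762128	11764128
2	14008104	14010104
2	14385614	14387614
2	15005747	15007747
2	15263013	15265013
2	15330788	15332788
2	15355857	15357857
2	15842744	15844744
2	16221382	16223382
2	17371294	17373294
2	17633234	17635234
2	17700110	17702110
2	19264238	19266238
2	19284504	19286504
2	21324759	21326759
2	21612295	21614295
2	21833759	21835759
2	22613338	22615338
2	22838859	22840859
2	23366336	23368336
2	23513193	23515193
2	25519748	25521748
2	25731720	25733720
2	26655044	26657044
2	26973836	26975836
2	28327475	28329475
2	28714181	28716181
2	28846936	28848936
2	28940573	28942573
2	30421988	30423988
2	30845227	30847227
2	30929225	30931225
2	30975205	30977205
2	31061160	31063160
2	31434856	31436856
2	31898455	31900455
2	31961269	31963269
2	32297635	32299635
2	32322319	32324319
2	33656948	33658948
2	33961584	33963584
2	34348840	34350840
2	34847097	34849097
2	35798393	35800393
2	36283814	36285814
2	36402599	36404599
2	36816208	36818208
2	36987792	36989792
2	37725150	37727150
2	38132857	38134857
2	38610852	38612852
2	40461740	40463740
2	41517720	41519720
2	42058797	42060797
2	42571905	42573905
2	43126945	43128945
2	44124996	44126996
2	44204180	44206180
2	44324642	44326642
2	46752354	46754354
2	46897663	46899663
2	46937014	46939014
2	46985276	46987276
2	47393642	47395642
2	47611581	47613581
2	47902905	47904905
2	49182929	49184929
2	49375365	49377365
2	49731965	49733965
2	49768418	49770418
2	52115060	52117060
2	52200539	52202539
2	52266750	52268750
2	53004701	53006701
2	53124863	53126863
2	53175345	53177345
2	54900328	54902328
2	56801357	56803357
2	57068573	57070573
2	57376671	57378671
2	57666472	57668472
2	57744206	57746206
2	57979171	57981171
2	57995080	57997080
2	58768188	58770188
2	59380365	59382365
3	195763	197763
3	1248439	1250439
3	1846862	1848862
3	2571948	2573948
3	3113461	3115461
3	3172321	3174321
3	3644441	3646441
3	4662142	4664142
3	7200852	7202852
3	7245204	7247204
3	7642925	7644925
3	8276778	8278778
3	8438069	8440069
3	8492848	8494848
3	8794223	8796223
3	9011919	9013919
3	10839155	10841155
3	11018838	11020838
3	12201267	12203267
3	12604787	12606787
3	14950823	14952823
3	17094615	17096615
3	17561693	17563693
3	17704066	17706066
3	18247581	18249581
3	20586715	20588715
3	20673587	20675587
3	20935508	20937508
3	21326154	21328154
3	21387929	21389929
3	21966124	21968124
3	22548247	22550247
3	22646435	22648435
3	23273073	23275073
3	24144323	24146323
3	24572515	24574515
3	25515288	25517288
3	25954568	25956568
3	29474805	29476805
3	29517018	29519018
3	29798004	29800004
3	30748262	30750262
3	30909262	30911262
3	31013032	31015032
3	32572250	32574250
3	32695400	32697400
3	33126956	33128956
3	33256422	33258422
3	33557265	33559265
3	33564122	33566122
3	34912847	34914847
3	35133815	35135815
3	35868977	35870977
3	37204970	37206970
3	37537710	37539710
3	38262325	38264325
3	39333804	39335804
3	39564656	39566656
3	39864032	39866032
3	39945410	39947410
3	40262527	40264527
3	41426312	41428312
3	44097827	44099827
3	45380572	45382572
3	47441925	47443925
3	47985954	47987954
3	48066889	48068889
3	48291155	48293155
3	48549180	48551180
3	48658119	48660119
3	48690204	48692204
3	49123962	49125962
3	49127322	49129322
3	49766681	49768681
3	50263532	50265532
3	52709484	52711484
3	53323494	53325494
3	53418603	53420603
3	54613033	54615033
3	55350915	55352915
3	55733878	55735878
3	56225182	56227182
3	56816302	56818302
3	56881452	56883452
3	57500133	57502133
3	57556390	57558390
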