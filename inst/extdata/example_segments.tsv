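sample	chrom	start	end	major_cn	minor_cn
HRD_001	1	17869241	18114894	0	0
HRD_001	2	41017506	45109831	1	0
HRD_001	2	37588962	42276484	1	0
HRD_001	1	20595951	55974407	1	0
HRD_001	2	17562999	17647661	2	0
HRD_001	1	14453139	17141957	2	0
HRD_001	2	33467193	41581274	2	0
HRD_001	3	3332054	17341770	2	0
HRD_001	1	26526791	46764772	4	0
HRD_001	1	6369480	45515735	4	0
HRD_001	1	1694310	55861268	3	0
HRD_001	1	10253694	56597781	4	0
HRD_001	3	10865063	11426966	8	0
HRD_001	2	59226398	59847564	11	0
HRD_001	2	27824293	30883635	10	0
HRD_001	1	49566743	53162407	11	0
HRD_001	2	26149725	28827530	12	0
HRD_001	2	53272881	53282512	1	1
HRD_001	2	17331665	17641617	1	1
HRD_001	3	13733619	17292334	1	1
HRD_001	1	52737698	52739553	2	2
HRD_001	1	38439297	45894792	3	1
HRD_001	3	12514481	51589739	2	1
HRD_001	1	1301216	54631960	3	1
HRD_001	2	33509893	33599169	6	6
HRD_001	2	24151011	30077661	8	1
HRD_001	1	22754252	30073888	8	3
HRD_001	3	30786040	40528062	6	4
HRD_001	3	34944537	51630265	10	1
HRD_002	1	24033084	30449888	1	0
HRD_002	3	49943925	51056809	1	0
HRD_002	1	1044801	55826738	1	0
HRD_002	2	3006521	49538040	1	0
HRD_002	1	26631253	26667864	2	0
HRD_002	1	378186	381964	2	0
HRD_002	2	22323428	25459384	2	0
HRD_002	1	31708613	31786612	3	0
HRD_002	3	56193915	56278519	4	0
HRD_002	2	1176871	1573618	6	0
HRD_002	3	3447705	29220413	7	0
HRD_002	2	7986990	58724025	7	0
HRD_002	3	11819854	41205342	12	0
HRD_002	3	17667386	58384203	9	0
HRD_002	2	972820	15740352	1	1
HRD_002	3	20522822	39435911	1	1
HRD_002	3	24100796	36207864	5	2
HRD_002	3	1605663	19816646	5	1
HRD_002	3	83729	53802359	4	4
HRD_002	2	9542096	54753031	3	3
HRD_002	1	15947631	16235997	8	4
HRD_003	1	21729909	22408312	1	0
HRD_003	3	41849191	48030791	1	0
HRD_003	2	39197899	47988346	1	0
HRD_003	3	27577040	56050894	1	0
HRD_003	3	6113182	43027385	1	0
HRD_003	2	3044091	3292279	2	0
HRD_003	2	51481962	52425623	2	0
HRD_003	2	13333101	55339431	2	0
HRD_003	2	3462733	5875196	3	0
HRD_003	3	16671	20407868	4	0
HRD_003	1	13290679	36484693	3	0
HRD_003	2	15766735	37101663	8	0
HRD_003	1	15257362	42234489	6	0
HRD_003	3	6659159	34958803	7	0
HRD_003	2	9237334	52274187	8	0
HRD_003	1	43000398	43060935	10	0
HRD_003	1	33683934	41151629	1	1
HRD_003	1	8022589	50791686	1	1
HRD_003	1	21286397	21376872	2	1
HRD_003	2	21759227	47252484	9	3
HRD_003	3	3217941	28081441	8	4
HRD_003	3	1547109	54014893	9	3
HRD_003	1	13508899	59628270	9	3
HRD_003	3	3367756	55933615	7	2
HRD_004	2	25312046	25401792	0	0
HRD_004	3	55037036	55964785	0	0
HRD_004	3	3142737	32421431	0	0
HRD_004	3	4443662	33338416	0	0
HRD_004	1	17627720	23181577	1	0
HRD_004	1	6667782	40659638	1	0
HRD_004	1	31728141	37628348	2	0
HRD_004	1	46553012	49183143	2	0
HRD_004	3	39050854	54564061	2	0
HRD_004	2	2433982	54292915	2	0
HRD_004	3	11688770	58354184	2	0
HRD_004	3	47955884	48019116	4	0
HRD_004	3	38141697	48043713	4	0
HRD_004	3	31029707	35007988	4	0
HRD_004	3	617447	5051346	6	0
HRD_004	2	25136908	37994639	7	0
HRD_004	1	28678692	44276165	8	0
HRD_004	2	8633980	55125470	7	0
HRD_004	1	41040901	45311313	12	0
HRD_004	3	11193340	20850554	12	0
HRD_004	1	20656066	36099068	10	0
HRD_004	3	18712754	19046118	1	1
HRD_004	2	18463140	22135373	2	2
HRD_004	2	31570031	45699697	2	1
HRD_004	2	4295639	55063294	2	2
HRD_004	1	7712709	50648468	2	1
HRD_004	3	22218003	31997055	5	2
HRD_004	3	16009308	16423239	9	2
HRD_004	1	35112498	43809934	8	4
HRD_004	3	5783191	31173493	7	3
HRD_004	1	5376172	59461359	8	3
HRP_001	1	31529522	32320238	0	0
HRP_001	3	1183653	55156899	1	0
HRP_001	3	4264316	11141458	2	0
HRP_001	2	6410850	12155851	2	0
HRP_001	3	1316547	20553463	2	0
HRP_001	2	2153317	44993228	2	0
HRP_001	3	36912132	36936869	3	0
HRP_001	1	38569591	39499461	4	0
HRP_001	3	11166852	46279891	4	0
HRP_001	2	18079645	59775602	3	0
HRP_001	3	1925038	40326865	7	0
HRP_001	2	36948816	59607759	5	0
HRP_001	2	24791155	24878833	11	0
HRP_001	1	15455305	32607451	12	0
HRP_001	2	2506760	55583243	12	0
HRP_001	2	30785405	31500730	1	1
HRP_001	1	19439866	23444682	1	1
HRP_001	1	3732413	21000447	1	1
HRP_001	1	3514314	58267180	1	1
HRP_001	1	1281539	41669791	1	1
HRP_001	1	50453826	50512820	2	1
HRP_001	3	53093746	54081390	2	1
HRP_001	3	1595948	55495986	2	2
HRP_001	1	20791570	21495105	4	1
HRP_001	1	20530130	20746891	5	1
HRP_001	3	28185795	28811818	6	1
HRP_001	3	16500363	50884190	5	2
HRP_001	1	8582398	55236865	6	2
HRP_001	1	7351597	54398746	5	3
HRP_002	1	45090494	45187016	1	0
HRP_002	3	41601171	41680040	1	0
HRP_002	1	44824690	44872528	1	0
HRP_002	1	19763378	40635503	1	0
HRP_002	2	22183433	41638372	1	0
HRP_002	1	8635006	8705747	4	0
HRP_002	3	35328768	39380920	3	0
HRP_002	1	2996692	49161956	4	0
HRP_002	2	45807560	47658826	7	0
HRP_002	3	16753849	23067147	6	0
HRP_002	1	1296552	10041644	7	0
HRP_002	3	53263215	56431960	7	0
HRP_002	2	4774055	55909234	12	0
HRP_002	1	10565312	16698431	1	1
HRP_002	2	5114147	56752866	1	1
HRP_002	1	1843525	40502420	2	1
HRP_002	3	14791065	52696489	2	2
HRP_002	3	13201079	59568235	2	1
HRP_002	1	58323898	58372644	3	3
HRP_002	2	15577757	26462300	5	3
HRP_002	2	24291110	58211189	5	1
HRP_002	3	1628885	47388063	3	3
HRP_002	2	10664042	56986686	9	2
HRP_003	2	35665302	35683084	0	0
HRP_003	2	39008525	39049014	0	0
HRP_003	3	1032247	18016073	0	0
HRP_003	1	27218621	32566144	1	0
HRP_003	1	12811720	59869134	1	0
HRP_003	2	32463176	32694518	2	0
HRP_003	2	4564210	31249382	6	0
HRP_003	1	40629064	47797387	12	0
HRP_003	1	18207010	38149269	9	0
HRP_003	3	9510904	35785401	9	0
HRP_003	3	22863420	23777092	1	1
HRP_003	1	3999751	23875270	1	1
HRP_003	1	9841441	56254814	2	2
HRP_003	2	9728286	59334762	3	1
HRP_003	1	1235548	41759789	2	1
HRP_003	1	50118272	50162937	5	1
HRP_003	3	10078843	10456425	7	1
HRP_003	1	10905236	53522701	4	2
HRP_003	1	59033733	59038364	8	1
HRP_003	2	34451224	34481061	6	5
HRP_003	2	19632793	19704293	6	4
HRP_003	2	10408233	11285388	11	1
HRP_003	3	3173764	46076641	6	3
HRP_004	3	48962367	49040103	0	0
HRP_004	2	58218194	59160866	0	0
HRP_004	1	28630775	29129134	0	0
HRP_004	3	4915604	53853292	1	0
HRP_004	2	3963160	58960741	1	0
HRP_004	3	4094009	44335103	2	0
HRP_004	2	48108624	48205586	4	0
HRP_004	1	49084389	55592149	3	0
HRP_004	1	50178125	50259896	7	0
HRP_004	1	28904972	28958847	6	0
HRP_004	2	3409586	4261245	6	0
HRP_004	2	765441	2093356	6	0
HRP_004	2	8719412	49978774	8	0
HRP_004	3	53245161	53569914	9	0
HRP_004	3	4692399	58212167	12	0
HRP_004	3	3445197	3511324	1	1
HRP_004	3	30563419	33773825	1	1
HRP_004	3	974426	5124410	1	1
HRP_004	3	22602879	55315939	2	2
HRP_004	2	36356636	36416478	5	1
HRP_004	3	22337533	44443793	6	2
HRP_004	1	46762002	47011235	10	2
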