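gene_id	SMP001	SMP002	SMP003	SMP004	SMP005	SMP006	SMP007	SMP008
G00001	37.2399772743131	14.4807341421303	519.491221747246	134.816851486163	157.746586931516	155.350147916093	358.72244802805	182.157062278783
G00002	205.416409133558	23.3695961649632	439.541919390574	66.9678847681753	159.806314262357	149.625363869033	341.911934429105	74.5573231023776
G00003	62.670654465321	16.9064719647887	288.730302456224	65.5355271563543	109.069583399071	59.888887124527	632.504488161229	48.0486252010696
G00004	90.7543507723534	13.3249036596713	145.508678941958	65.1674969727695	261.84246893427	128.574605669204	215.552079089866	316.83166088244
G00005	65.5510853936176	45.9096922779787	91.8306815025312	54.3897450477164	25.0794034688194	507.489670885363	546.593587635323	509.618830813075
G00006	94.6867848433457	269.339140356091	155.547360966222	80.1500852975609	74.9270583475892	73.643364487397	373.007901660868	82.2865847794528
G00007	152.353215802876	465.556053710264	193.568892837292	98.6989722210233	182.036168167204	204.463435257852	881.636515228337	61.529860578278
G00008	1013.56164538941	101.59802737572	236.403166859232	775.506417777166	311.303827192311	85.6453624230167	27.053301983639	61.7566864612749
G00009	672.93692317713	184.333254626779	145.706468639805	736.395089760652	746.783552000261	78.0567672835294	18.7305420508226	42.5476314647729
G00010	416.844011582675	532.164259617155	313.952933460006	782.816830148096	868.95233471071	54.8007849585433	62.0366341140986	85.0032131732137
G00011	556.153889957825	191.918167931524	148.817375290009	596.320153598254	919.401517353596	64.137435363954	58.8216722069377	89.07759815844
G00012	26.1358279385144	154.71293419171	537.816407607935	269.02968701332	309.002334067497	677.317730907716	819.579024126593	163.547359441507
G00013	63.006309485465	18.6590982918691	106.534933861187	1287.23518587392	121.956620598985	139.444312223486	389.586877417086	167.306822908413
G00014	281.66136628464	25.9957530874465	222.231004470141	45.7192986139329	325.355274344664	33.1781079047473	153.951666743267	30.0297143946748
G00015	241.013710991374	20.5487769162777	141.090260031604	64.2458204649469	226.936517632643	127.251350355872	251.368805522764	193.773101877876
G00016	128.429313743509	28.4732262684041	313.73030472053	112.706833311139	198.208522469506	17.9926456476851	354.861913059498	78.1445475378022
G00017	179.877965920432	407.029089369898	109.591862195707	178.888949950129	256.124564220896	283.966133589317	180.239840334994	197.409596474328
G00018	151.680033115817	410.414275251514	162.181180957133	846.657213261453	285.552661669378	831.374120591584	196.479885352446	126.857916196861
G00019	129.266122184221	91.1605422408902	353.42426169935	491.423009170409	64.6622780009869	424.070011256584	221.033685004295	304.766349305727
G00020	67.2262367705726	20.4591787088555	480.857707501445	80.9554986754625	83.7839231213419	62.6453996881602	148.083530916278	130.985823663216
G00021	28.1368587154152	30.203637541642	573.999955291365	164.792626489613	96.4722796947453	257.13626259852	165.952609897093	55.8346048001082
G00022	50.5980989833585	13.3354646602406	437.247180111048	166.163325426683	83.2655115307722	214.302755386514	449.841733029395	186.052062833956
G00023	57.3230589907986	18.4809472462814	492.36901824083	111.264506862737	63.3408494057093	108.278347959943	233.684656307989	64.4201122560859
G00024	185.511814304531	78.0489215255652	87.2573264728943	49.6450731447892	12.9368979335917	585.097832443955	287.142871864518	859.481746079745
G00025	135.499012462587	33.6184955843839	44.7507732080623	236.423154810714	11.0751859218827	594.825438598964	300.630977748126	1014.80354774473
G00026	113.836434044576	49.1675042881078	21.1154396997114	89.1308318738915	24.4953874062298	461.118133186935	300.310018351673	721.130953995462
G00027	363.121070204772	39.8456824393344	29.5064481371966	46.6970728317823	46.1502576163735	294.588466156019	173.092570883707	1143.3802581588
G00028	57.5580421617026	26.0405708075946	170.032708884809	94.1471753803545	148.75636763225	108.547150812045	96.7586510076189	65.3357319583938
G00029	12.5750607868046	14.5658585617433	940.586826673562	96.0955905227164	35.7700327108482	173.198586373326	110.719656258116	160.796556884209
G00030	112.638210884818	11.658339866361	338.362994741149	66.4902758246675	84.8191348799263	250.587472210137	307.611931664134	76.252606920784
G00031	72.4033191232103	101.731164124517	127.224724760102	1321.0821261775	96.9020617890886	148.769878858371	62.8592938084038	226.242385109735
G00032	136.019458468518	138.556615428789	69.9452109690357	152.968087778375	65.1775113036872	100.447303503384	55.2859097642326	507.678791262702
G00033	106.323549600481	60.0391527136808	120.734834744952	96.9398017653245	23.3562916080202	465.269152148474	178.519354490968	234.403067012377
G00034	58.5480582739908	52.9486292327299	90.7921393294853	714.03961032641	65.545516180582	81.6066736569276	43.0314089186826	108.697469425292
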