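chrom	start	end	size	shared_start	shared_end	shared_size	reduction_bp
1	149241884	149992523	750639	149547998	149960460	412462	338177
2	70314631	71161113	846482	70314631	71161113	846482	None
3	76084701	76781970	697269	76084701	76413468	328767	368502
3	98862402	99422213	559811	98862402	99283161	420759	139052
5	43230619	44574214	1343595	43834751	44574214	739463	604132
5	48477903	49268610	790707	48477903	49212943	735040	55667
5	62272683	62659987	387304	62272683	62587423	314740	72564
7	31748136	33875610	2127474	32640500	33093884	453384	1674090
7	50281923	50809190	527267	50281923	50670070	388147	139120
7	62415406	63117931	702525	62551178	62782874	231696	470829
11	61877437	62548419	670982	62343547	62548419	204872	466110
12	27050192	29151436	2101244	28949354	29151436	202082	1899162
13	18130223	18421481	291258	18132557	18320265	187708	103550
16	24517859	25540339	1022480	25389029	25540339	151310	871170
16	50610769	50762363	151594	50610769	50762363	151594	None
19	2568979	2765065	196086	2568979	2765065	196086	None
19	26909816	27143239	233423	27004483	27143239	138756	94667
19	44788419	45414418	625999	44788419	44924467	136048	489951
19	46031543	46786391	754848	46580102	46673984	93882	660966
21	33590777	33696403	105626	33590777	33696403	105626	None
22	45102551	46400273	1297722	45231901	46126149	894248	403474
24	61008938	62530799	1521861	61972128	62530799	558671	963190
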