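# Synthetic trinucleotide property table: fixed placeholder values in [0,1],
# not a curated physicochemical set. Supply a curated table for real analyses.
oligo	sp01	sp02	sp03	sp04	sp05	sp06	sp07	sp08	sp09	sp10	sp11
AAA	0.6672	0.7436	0.8469	0.2322	0.805	0.0443	0.2353	0.1615	0.8009	0.9302	0.7137
AAC	0.2926	0.2902	0.4099	0.3541	0.5013	0.7402	0.4757	0.9138	0.5743	0.4844	0.3599
AAG	0.8942	0.7958	1	0.0759	0.2673	0.617	0.2434	0.858	0.425	0.4484	0.4876
AAT	1	0.7497	0.1043	0.4989	0.2561	0.0661	0.0283	0.6312	0.8889	0.5429	0.3983
ACA	0.9098	0.4069	0.8358	0.0178	1	0.5176	0.3963	0.4523	1	0.5074	0.8969
ACC	0.5339	0.9433	0.8009	0.2954	0.5751	0.73	0.7811	0.4562	0.7914	0.2527	0.1232
ACG	0.8967	0.3768	0.9093	0.7007	0.0186	0.6513	1	0.4714	0.366	0.4819	0.3831
ACT	0.4922	0.1217	0.6254	0.9124	0.7913	0.4031	0.9979	0.9289	0.7539	0.5297	0.5806
AGA	0.5509	0.9362	0.8734	0.3838	0.1357	0.2555	0.9635	1	0.5172	0.7472	0.5719
AGC	0.431	0.0085	0.6913	0.1272	0.3965	0.7517	0.4666	0.9517	0.4407	0.3072	0.4449
AGG	0.2384	0.1455	0.5553	0.2666	0.2701	0.3654	0.1418	0.5119	0.2295	0.6784	0.3602
AGT	0.4053	0.1048	0.5697	0.4389	0.3519	0.4141	0.0051	0.8357	0.1896	0.1343	0.0815
ATA	0.1091	0.4881	0.8862	0.7569	0.1937	0.3013	0.8059	0.0112	0.9118	0.9428	0.739
ATC	0.6655	0.1016	0.9033	0.7187	0.6846	0.9034	0.0126	0.1357	0.1816	0.1998	0.4445
ATG	0.7822	0.8756	0.2488	0.8455	0.5632	0.3774	0.7229	0.1421	0.9756	0.6437	0.3615
ATT	0.7219	0.3964	0.7297	0.037	0.9476	1	0.8022	0.4176	0.7915	0.3378	0.5907
CAA	0.899	0.7059	0.2291	0.1318	0.9374	0.7032	0.7868	0.7278	0.3088	0.1453	0.5051
CAC	0.0997	0.2981	0.8924	0.79	0.3106	0.191	0.5641	0.5497	0.6431	1	0.2058
CAG	0.0546	0.2666	0.7824	0.6834	0.4676	0.9585	0.6635	0.2128	0.0917	0.6424	0.7241
CAT	0.9236	0.701	0.6919	0.5487	0.4869	0.4641	0.4809	0.2418	0.0549	0.6747	0.2219
CCA	0.6202	0.0719	0.1055	0.783	0.7594	0.8999	0.5172	0.2841	0.5394	0.6812	0.9786
CCC	0.6993	0.2192	0.5222	0.2943	0.0075	0.3935	0.7951	0.4416	0.081	0.5226	0.8806
CCG	0.5852	0.777	0.1452	0.5278	0.7118	0.5368	0.0827	0.3425	0.0994	0.8847	0
CCT	0.6748	0.0103	0.8207	0.1546	0.9974	0.9053	0.3651	0.3886	0.5615	0.0011	0.3396
CGA	0.737	0.9979	0.4018	0.2371	0.2443	0.4672	0.5937	0.3805	0.3451	0.5281	0.4845
CGC	0.8089	0.9849	0.8839	0.471	0.7142	0	0.0361	0.1907	0.8064	0.2889	0.5922
CGG	0.2423	0.2643	0.7864	0.1275	0.4002	0.9507	0.2351	0.636	0.9406	0.9696	0.7512
CGT	0.4501	0.1374	0.8298	0.226	0	0.8316	0.0847	0.7213	0.0686	0.9584	0.6627
CTA	0.9084	0.601	0.7395	0.0704	0.6404	0.4143	0.0108	0.1663	0.5837	0.3799	0.5179
CTC	0.1995	0.1034	0.6455	0.8248	0.9651	0.8202	0.9663	0.0727	0.6503	0.7016	0.8153
CTG	0.9877	0.6474	0.1722	0.877	0.2761	0.3552	0.4898	0.1701	0.3492	0.9231	0.9638
CTT	0.7324	0.1407	0.626	0.0097	0.1761	0.6227	0.8089	0.6674	0.5632	0.7326	0.1087
GAA	0.9106	0.0619	0.0065	1	0.1886	0.507	0.2309	0.5826	0.1701	0.051	0.6971
GAC	0.5651	0.9633	0.3049	0.5186	0.0271	0.1129	0.9414	0.5426	0.5818	0.7382	0.6811
GAG	0.1325	0.2285	0.6803	0.9956	0.5152	0.974	0.8841	0.7953	0.6521	0.1093	0.5854
GAT	0.1454	0.3581	0.5785	0.1307	0.184	0.9889	0.4472	0.9322	0.0057	0.2541	0.2898
GCA	0.6246	0.7385	0.9471	0.1981	0.4002	0.0881	0.2619	0.5005	0.1901	0.3533	0.491
GCC	0.0756	0.4088	0.5531	0.7225	0.4397	0.9592	0.5044	0.4392	0.6988	0.5	0.4649
GCG	0.5637	0.8257	0.3678	0.3001	0.4722	0.2284	0.7332	0.1219	0.8825	0.713	0.4195
GCT	0.0461	0.8361	0.7051	0.9395	0.3473	0.6297	0.6456	0.6788	0.0145	0.2153	0.7968
GGA	0.0857	0.8524	0.2476	0.3141	0.8149	0.1844	0.6596	0.0226	0.2769	0.1879	0.9228
GGC	0.3711	0.3381	0.2269	0.2295	0.9266	0.0336	0.721	0.2119	0.1585	0.338	0.0823
GGG	0	0.4376	0.0894	0.2429	0.0454	0.8035	0.7983	0.506	0.5491	0.6564	0.533
GGT	0.2997	0.7122	0.7679	0.6594	0.3325	0.5946	0	0.6843	0	0.5571	0.9798
GTA	0.8877	0.4836	0.4248	0.324	0.1268	0.2025	0.342	0.2251	0.1141	0.1611	0.3103
GTC	0.7522	0.8657	0.5369	0.2866	0.0374	0.7825	0.0398	0.2252	0.4565	0.5676	0.7548
GTG	0.1094	0.0992	0.6995	0.3626	0.3727	0.4269	0.999	0.907	0.5443	0.0596	0.1005
GTT	0.6666	0.9883	0.1882	0.8051	0.6807	0.7826	0.8797	0.1402	0.8103	0.7761	0.0113
TAA	0.7137	0.1557	0.3593	0.2546	0.7089	0.3488	0.4042	0.6483	0.7785	0.8856	0.8158
TAC	0.2404	0.4685	0.9364	0.6641	0.3111	0.376	0.7372	0.2066	0.5328	0.9583	0.8845
TAG	0.2752	0.5956	0.3853	0.3635	0.6446	0.007	0.5518	0.3559	0.6728	0.8296	0.8575
TAT	0.679	0.5021	0	0.9441	0.8591	0.3853	0.6547	0.0518	0.5529	0.9415	0.7848
TCA	0.7287	0.8665	0.1027	0.9674	0.884	0.1399	0.3454	0.0521	0.3263	0.8306	0.7584
TCC	0.7194	0.4121	0.6995	0.3496	0.775	0.8658	0.366	0.4931	0.6283	0.3238	0.1653
TCG	0.9513	0.281	0.5327	0.5477	0.1919	0.3831	0.4047	0.5698	0.4315	0.2392	0.169
TCT	0.2102	0.6318	0.649	0	0.245	0.8219	0.963	0.2447	0.0351	0.0393	0.8045
TGA	0.4441	0.6553	0.662	0.7475	0.0636	0.6658	0.8067	0	0.2371	0.5169	0.7466
TGC	0.8994	0.4283	0.0787	0.4988	0.1917	0.4062	0.2914	0.1757	0.3711	0.35	0.7346
TGG	0.0559	0.9891	0.5049	0.1979	0.9006	0.8272	0.4005	0.5246	0.6497	0.8155	0.2274
TGT	0.778	0.2064	0.6553	0.9879	0.3374	0.4308	0.4172	0.3141	0.0085	0	0.6607
TTA	0.1317	0	0.3068	0.8596	0.7473	0.8932	0.6176	0.2492	0.9069	0.5732	0.7464
TTC	0.2479	0.1226	0.3178	0.1395	0.4549	0.7045	0.5973	0.5182	0.9402	0.921	0.7226
TTG	0.8448	1	0.5547	0.767	0.4959	0.126	0.6593	0.4166	0.7256	0.8163	1
TTT	0.6321	0.8597	0.5587	0.6633	0.5363	0.8514	0.7308	0.0011	0.6386	0.5593	0.3413
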