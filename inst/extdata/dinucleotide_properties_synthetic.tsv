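# Synthetic dinucleotide property table: fixed placeholder values in [0,1],
# not a curated physicochemical set. Supply a curated table for real analyses.
oligo	sp01	sp02	sp03	sp04	sp05	sp06	sp07	sp08	sp09	sp10	sp11	sp12	sp13	sp14	sp15
AA	0.7574	0.785	0.0109	0.2444	0.6606	0.5983	0.1199	0.6873	0.9546	0.0705	0.086	0.1952	0.0062	0.7838	0.6571
AC	0	0.3848	0.3582	0.9685	0.8811	0.7921	0	0.3016	0.4903	0.3472	0.9482	0.8332	0.1023	1	1
AG	1	0.0917	0.1848	0.8345	0.1142	0.8422	0.0701	0.8055	0	0.8525	0.5037	0.0411	0.281	0.9178	0.4664
AT	0.268	0.5594	0.6926	0.4553	0.344	0.3104	0.9845	0.084	0.1285	0.8127	0.5915	1	0.2459	0	0.4536
CA	0.1437	0.5638	0.0037	0	0.1907	0.7366	0.8717	0	0.9202	0.5074	0.4665	0.9444	1	0.4501	0.1427
CC	0.5104	0.6312	0.581	0.9585	0.4975	0.7419	0.3109	0.3983	0.5577	0.6962	0.6951	0.345	0.5492	0.804	0.0808
CG	0.8047	0.9056	0.3862	0.5749	0.6381	0.8222	0.4817	0.624	0.1979	0.8142	0.9627	0.241	0.2164	0.8826	0.3659
CT	0.8056	0.2606	0.4666	0.5482	0.7714	0.5653	0.1355	1	0.3207	0.533	1	0.1788	0.8301	0.7133	0.2073
GA	0.1763	0.6404	0.4343	0.8137	0.3271	0	0.6576	0.7885	0.4699	0.2813	0.5002	0.124	0.8795	0.264	0.7844
GC	0.8572	0.0819	0	0.3545	0.8566	0.1358	1	0.2094	0.7513	0.3969	0.7438	0.1832	0.2015	0.1734	0.7523
GG	0.8924	0.3575	0.7821	0.9778	1	0.7171	0.3159	0.5983	0.0737	0.9569	0.1363	0.0161	0.0589	0.4089	0.7828
GT	0.3748	1	0.3435	0.5421	0.851	0.2599	0.2082	0.3602	1	0.9974	0.5909	0.3693	0.0236	0.2168	0.3947
TA	0.254	0.3814	0.3204	1	0.6244	0.521	0.9272	0.8531	0.8494	0	0.1811	0	0.4158	0.1068	0
TC	0.4969	0.4692	0.3116	0.0809	0	1	0.971	0.7292	0.3219	0.7231	0.4937	0.0133	0.9316	0.574	0.9302
TG	0.666	0.1692	0.3523	0.6802	0.6335	0.0871	0.1252	0.336	0.1977	1	0	0.5184	0	0.5665	0.4124
TT	0.6419	0	1	0.9302	0.4374	0.4072	0.8773	0.0716	0.6762	0.5963	0.548	0.6827	0.5895	0.1911	0.3567
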