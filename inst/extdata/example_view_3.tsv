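V1	V2	V3	V4	V5	V6	V7	V8	V9	V10	V11	V12	V13	V14	V15	V16
0.0000	0.6484	0.5778	0.5634	0.6228	0.7096	0.5680	0.6643	0.2299	0.2406	0.2269	0.3360	0.1480	0.2977	0.1902	0.1585
0.6484	0.0000	0.6646	0.5252	0.7670	0.5267	0.6200	0.6687	0.1843	0.1681	0.2176	0.1851	0.1214	0.2809	0.1467	0.1281
0.5778	0.6646	0.0000	0.5848	0.6652	0.6384	0.7224	0.6100	0.1519	0.2958	0.2804	0.1284	0.0000	0.2085	0.2388	0.2567
0.5634	0.5252	0.5848	0.0000	0.7603	0.7377	0.6982	0.6585	0.2259	0.3205	0.2072	0.1615	0.2236	0.1522	0.2618	0.2652
0.6228	0.7670	0.6652	0.7603	0.0000	0.6102	0.5909	0.6635	0.1496	0.3797	0.3034	0.1902	0.2142	0.1283	0.2524	0.1952
0.7096	0.5267	0.6384	0.7377	0.6102	0.0000	0.7568	0.5957	0.3528	0.0000	0.2482	0.2213	0.1749	0.2318	0.1634	0.1174
0.5680	0.6200	0.7224	0.6982	0.5909	0.7568	0.0000	0.7190	0.1113	0.0970	0.2307	0.2143	0.2205	0.2233	0.3618	0.2036
0.6643	0.6687	0.6100	0.6585	0.6635	0.5957	0.7190	0.0000	0.1431	0.1471	0.2283	0.2439	0.1560	0.0956	0.1311	0.2816
0.2299	0.1843	0.1519	0.2259	0.1496	0.3528	0.1113	0.1431	0.0000	0.5905	0.6719	0.6743	0.7953	0.6354	0.6040	0.4384
0.2406	0.1681	0.2958	0.3205	0.3797	0.0000	0.0970	0.1471	0.5905	0.0000	0.7194	0.6830	0.5908	0.6288	0.7027	0.7694
0.2269	0.2176	0.2804	0.2072	0.3034	0.2482	0.2307	0.2283	0.6719	0.7194	0.0000	0.6398	0.6967	0.6694	0.7742	0.4686
0.3360	0.1851	0.1284	0.1615	0.1902	0.2213	0.2143	0.2439	0.6743	0.6830	0.6398	0.0000	0.6099	0.5138	0.6188	0.6427
0.1480	0.1214	0.0000	0.2236	0.2142	0.1749	0.2205	0.1560	0.7953	0.5908	0.6967	0.6099	0.0000	0.7281	0.5973	0.6942
0.2977	0.2809	0.2085	0.1522	0.1283	0.2318	0.2233	0.0956	0.6354	0.6288	0.6694	0.5138	0.7281	0.0000	0.6516	0.6725
0.1902	0.1467	0.2388	0.2618	0.2524	0.1634	0.3618	0.1311	0.6040	0.7027	0.7742	0.6188	0.5973	0.6516	0.0000	0.5217
0.1585	0.1281	0.2567	0.2652	0.1952	0.1174	0.2036	0.2816	0.4384	0.7694	0.4686	0.6427	0.6942	0.6725	0.5217	0.0000
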