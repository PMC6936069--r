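V1	V2	V3	V4	V5	V6	V7	V8	V9	V10	V11	V12	V13	V14	V15	V16
0.0000	0.7103	0.6722	0.7798	0.7049	0.5622	0.6031	0.6219	0.1619	0.1706	0.0566	0.0896	0.3135	0.1136	0.1188	0.2424
0.7103	0.0000	0.7341	0.7149	0.5069	0.7436	0.5967	0.6732	0.1693	0.1883	0.1715	0.0816	0.2234	0.2826	0.1616	0.0563
0.6722	0.7341	0.0000	0.6793	0.5955	0.5299	0.6736	0.7619	0.2860	0.2227	0.2587	0.2305	0.2190	0.1694	0.0152	0.1958
0.7798	0.7149	0.6793	0.0000	0.5703	0.7835	0.5626	0.6303	0.1314	0.3242	0.3241	0.3077	0.1036	0.1132	0.1032	0.2145
0.7049	0.5069	0.5955	0.5703	0.0000	0.5293	0.7242	0.6566	0.2655	0.2830	0.2260	0.1686	0.2544	0.2567	0.2660	0.1539
0.5622	0.7436	0.5299	0.7835	0.5293	0.0000	0.6249	0.6673	0.0696	0.2264	0.2384	0.2105	0.1066	0.1307	0.1357	0.3578
0.6031	0.5967	0.6736	0.5626	0.7242	0.6249	0.0000	0.8031	0.2924	0.3062	0.2411	0.2347	0.0700	0.3893	0.1627	0.2048
0.6219	0.6732	0.7619	0.6303	0.6566	0.6673	0.8031	0.0000	0.2374	0.2267	0.2471	0.2123	0.1087	0.1465	0.2677	0.2211
0.1619	0.1693	0.2860	0.1314	0.2655	0.0696	0.2924	0.2374	0.0000	0.7276	0.6053	0.7907	0.6560	0.7307	0.7997	0.6417
0.1706	0.1883	0.2227	0.3242	0.2830	0.2264	0.3062	0.2267	0.7276	0.0000	0.5516	0.7389	0.5080	0.5083	0.6002	0.6318
0.0566	0.1715	0.2587	0.3241	0.2260	0.2384	0.2411	0.2471	0.6053	0.5516	0.0000	0.7586	0.6673	0.6890	0.8634	0.8846
0.0896	0.0816	0.2305	0.3077	0.1686	0.2105	0.2347	0.2123	0.7907	0.7389	0.7586	0.0000	0.7183	0.5887	0.7237	0.4948
0.3135	0.2234	0.2190	0.1036	0.2544	0.1066	0.0700	0.1087	0.6560	0.5080	0.6673	0.7183	0.0000	0.7092	0.5985	0.5983
0.1136	0.2826	0.1694	0.1132	0.2567	0.1307	0.3893	0.1465	0.7307	0.5083	0.6890	0.5887	0.7092	0.0000	0.6507	0.5654
0.1188	0.1616	0.0152	0.1032	0.2660	0.1357	0.1627	0.2677	0.7997	0.6002	0.8634	0.7237	0.5985	0.6507	0.0000	0.6877
0.2424	0.0563	0.1958	0.2145	0.1539	0.3578	0.2048	0.2211	0.6417	0.6318	0.8846	0.4948	0.5983	0.5654	0.6877	0.0000
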