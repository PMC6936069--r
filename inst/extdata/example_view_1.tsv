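V1	V2	V3	V4	V5	V6	V7	V8	V9	V10	V11	V12	V13	V14	V15	V16
0.0000	0.7430	0.6031	0.5434	0.4188	0.6484	0.6150	0.6384	0.0020	0.1269	0.2015	0.2045	0.2932	0.0912	0.0426	0.2088
0.7430	0.0000	0.7928	0.6143	0.5805	0.6380	0.7276	0.7078	0.1509	0.2996	0.2706	0.3063	0.1144	0.1976	0.2447	0.1912
0.6031	0.7928	0.0000	0.6956	0.6131	0.5997	0.6523	0.6796	0.1827	0.2070	0.2705	0.1674	0.2727	0.1807	0.1827	0.1652
0.5434	0.6143	0.6956	0.0000	0.6056	0.7559	0.6431	0.6306	0.3272	0.2339	0.2821	0.1345	0.0946	0.3538	0.1946	0.2441
0.4188	0.5805	0.6131	0.6056	0.0000	0.5283	0.6811	0.5322	0.3245	0.1345	0.1695	0.2287	0.2524	0.2078	0.2213	0.0788
0.6484	0.6380	0.5997	0.7559	0.5283	0.0000	0.6689	0.6023	0.2887	0.0766	0.2880	0.2047	0.1472	0.2074	0.3029	0.2677
0.6150	0.7276	0.6523	0.6431	0.6811	0.6689	0.0000	0.5583	0.1122	0.2445	0.1975	0.1944	0.2793	0.2151	0.2881	0.3378
0.6384	0.7078	0.6796	0.6306	0.5322	0.6023	0.5583	0.0000	0.0512	0.1705	0.2152	0.1692	0.1453	0.1490	0.1524	0.1239
0.0020	0.1509	0.1827	0.3272	0.3245	0.2887	0.1122	0.0512	0.0000	0.5662	0.7568	0.5801	0.7397	0.6471	0.6624	0.5260
0.1269	0.2996	0.2070	0.2339	0.1345	0.0766	0.2445	0.1705	0.5662	0.0000	0.7084	0.7457	0.6811	0.6590	0.6938	0.6026
0.2015	0.2706	0.2705	0.2821	0.1695	0.2880	0.1975	0.2152	0.7568	0.7084	0.0000	0.5171	0.6379	0.7469	0.6320	0.5755
0.2045	0.3063	0.1674	0.1345	0.2287	0.2047	0.1944	0.1692	0.5801	0.7457	0.5171	0.0000	0.6127	0.7652	0.7474	0.5327
0.2932	0.1144	0.2727	0.0946	0.2524	0.1472	0.2793	0.1453	0.7397	0.6811	0.6379	0.6127	0.0000	0.8267	0.7061	0.8033
0.0912	0.1976	0.1807	0.3538	0.2078	0.2074	0.2151	0.1490	0.6471	0.6590	0.7469	0.7652	0.8267	0.0000	0.7230	0.6436
0.0426	0.2447	0.1827	0.1946	0.2213	0.3029	0.2881	0.1524	0.6624	0.6938	0.6320	0.7474	0.7061	0.7230	0.0000	0.6200
0.2088	0.1912	0.1652	0.2441	0.0788	0.2677	0.3378	0.1239	0.5260	0.6026	0.5755	0.5327	0.8033	0.6436	0.6200	0.0000
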