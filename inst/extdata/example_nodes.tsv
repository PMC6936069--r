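node_id	x	y	z	label
V1	-6	26	9	moduleA
V2	-13	-32	-3	moduleA
V3	-2	-70	29	moduleA
V4	50	45	-25	moduleA
V5	41	-5	20	moduleA
V6	2	-84	61	moduleA
V7	-8	-17	-10	moduleA
V8	-19	-37	61	moduleA
V9	-58	55	-4	moduleB
V10	-46	28	-24	moduleB
V11	23	-1	28	moduleB
V12	-29	-36	2	moduleB
V13	-33	24	44	moduleB
V14	-19	-51	52	moduleB
V15	34	-16	34	moduleB
V16	41	29	-24	moduleB
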