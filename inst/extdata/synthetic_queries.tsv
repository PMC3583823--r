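id	label	fold	superfamily	family	f1	f2	f3	f4	f5	f6	f7	f8
q001	F03	F03	F03.S2	F03.S2.A2	5.1957834769348619	6.6431520746785218	0	5.5727023617148648	9.0554517807322785	6.4071426040786719	7.6973639631738013	6.2364900976245892
q002	F03	F03	F03.S1	F03.S1.A1	8.7813412531463655	7.2676907597797165	0.57030713757025797	5.5498364811253191	11.684131339439595	5.9501783779308326	8.2287077188516324	6.4668166725509098
q003	F06	F06	F06.S1	F06.S1.A1	0.94815365208269764	6.8615250695728784	9.4173315230451564	7.7892576536128777	10.283837574448576	8.6473417912768831	8.3502754012691938	7.2613632377224997
q004	F03	F03	F03.S1	F03.S1.A2	6.8630916407210627	6.6278893397656962	3.236688098399652	6.9584068092986131	11.091797792056276	5.7393941612613215	5.57774005151267	5.0165147434963346
q005	F06	F06	F06.S1	F06.S1.A1	2.8297499047710533	5.1681968771114501	7.6842860860444482	9.5330079033342869	9.958130092980813	9.1363870940268122	8.4614505035913385	8.0861562257896349
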