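locus_tag	start	end	strand	is_hp	label
syn_0000	1001	1900	+	0	known function
syn_0001	3401	4300	+	1	hsp
syn_0002	4351	5250	+	1	hsp
syn_0003	5301	6200	+	1	hsp
syn_0004	6251	7150	+	1	chaperone
syn_0005	7201	8100	+	1	hsp
syn_0006	14151	15050	+	0	known function
syn_0007	16551	17450	+	1	TRAM
syn_0008	17501	18400	+	1	TRAM
syn_0009	18451	19350	+	1	TRAM
syn_0010	19401	20300	+	1	cold shock protein
syn_0011	26351	27250	+	0	known function
syn_0012	28751	29650	-	1	dsr
syn_0013	29701	30600	-	1	dsr
syn_0014	30651	31550	-	1	dsr
syn_0015	31601	32500	-	1	dsr
syn_0016	32551	33450	-	1	dsr
syn_0017	39501	40400	+	0	known function
syn_0018	41901	42800	+	1	cbs
syn_0019	42851	43750	+	1	cbs
syn_0020	43801	44700	+	1	cbs
syn_0021	44751	45650	+	1	cbs
syn_0022	45701	46600	+	1	cbs
syn_0023	46651	47550	+	1	cbs
syn_0024	53601	54500	+	0	known function
syn_0025	56001	56900	-	1	anti-toxin
syn_0026	56951	57850	-	1	anti-toxin
syn_0027	57901	58800	-	1	anti-toxin
syn_0028	58851	59750	-	1	anti-toxin
syn_0029	65801	66700	+	0	known function
syn_0030	68201	69100	+	1	cas
syn_0031	69151	70050	+	1	cas
syn_0032	70101	71000	+	1	cas
syn_0033	71051	71950	+	1	cas
syn_0034	72001	72900	+	1	cas
syn_0035	72951	73850	+	1	cas
syn_0036	73901	74800	+	1	cas
syn_0037	74851	75750	+	1	cas
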