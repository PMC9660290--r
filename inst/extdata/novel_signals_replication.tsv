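category	chr	signal	index	closest_gene	d_bp	r2	pos_b37	ea	eaf	beta_gwas	se_gwas	p_gwas	beta_gcta	se_gcta	p_gcta	alpha_threshold	beta_ukbb	se_ukbb	p_ukbb
secondary	3	rs147877018	rs1397764	TFDP2	62539	0.031	141813349	A	0.081	-0.0047	0.0007	1.18E-12	-0.0035	0.0007	1.13E-07	1.33E-07	-0.0042	0.0006	1.80E-11
secondary	4	rs59664098	rs7667050	PPARGC1A	50300	0.001	23863409	A	0.070	-0.0037	0.0007	2.30E-07	-0.0038	0.0007	8.66E-08	1.31E-07	-0.0011	0.0007	8.70E-02
secondary	6	rs3904600	rs6921580	RREB1	-94049	0.107	7109665	C	0.370	0.0027	0.0004	4.91E-14	0.0018	0.0003	9.75E-08	1.37E-07	0.0030	0.0004	1.80E-16
secondary	7	rs12111979	rs700753	LOC730338	59613	0.170	46813297	T	0.420	0.0004	0.0003	2.38E-01	0.0017	0.0003	8.07E-08	1.39E-07	0.0007	0.0004	4.70E-02
secondary	8	rs4566	rs10086569	SLC7A13	-886127	0.002	86361082	T	0.610	0.0020	0.0004	1.03E-08	0.0019	0.0004	5.90E-08	7.37E-08	0.0011	0.0003	1.50E-03
secondary	12	rs2300127	rs11062167	SLC6A13	-49290	0.011	315449	T	0.570	0.0023	0.0004	1.62E-10	0.0019	0.0004	1.99E-07	2.35E-07	0.0008	0.0003	2.20E-02
secondary	12	rs11056376	rs10846157	RERG	-17637	0.020	15307394	A	0.910	0.0040	0.0007	5.43E-10	0.0034	0.0006	2.03E-07	2.36E-07	0.0021	0.0006	6.00E-04
secondary	12	rs3730071	rs2634675	ZNF641	427943	0.001	49168798	A	0.029	-0.0058	0.0011	1.86E-07	-0.0060	0.0011	7.20E-08	7.37E-08	-0.0040	0.0010	5.40E-05
secondary	16	rs438339	rs113956264	RPL3L	6421	0.001	2003425	T	0.880	0.0035	0.0007	5.36E-08	0.0034	0.0007	1.60E-07	4.17E-07	0.0010	0.0006	8.60E-02
tertiary	2	rs807574	rs807624	DDX1	24768	0.055	15807239	A	0.600	0.0011	0.0004	1.45E-03	0.0019	0.0003	8.09E-08	7.62E-07	0.0019	0.0004	9.90E-08
tertiary	7	rs13227214	rs3757387	IRF5	164269	0.057	128740355	C	0.460	-0.0024	0.0003	1.12E-12	-0.0018	0.0003	5.64E-08	2.40E-07	-0.0027	0.0003	6.60E-15
tertiary	9	rs7035892	rs2039424	PIP5K1B	107868	0.089	71540042	A	0.840	0.0053	0.0006	1.27E-17	0.0037	0.0006	1.23E-09	2.43E-07	-0.0016	0.0008	6.20E-02
tertiary	11	rs81205	rs233438	KCNQ1	4412	0.261	2798804	A	0.540	0.0034	0.0004	4.73E-20	0.0018	0.0003	1.28E-07	1.45E-06	0.0020	0.0004	3.50E-07
tertiary	11	rs294345	rs3925584	DCDC1	-93675	0.012	30666660	T	0.067	-0.0057	0.0007	2.32E-14	-0.0035	0.0007	3.01E-07	4.21E-07	-0.0001	0.0008	8.50E-01
tertiary	11	rs1193692	rs11227260	KAT5	42911	0.025	65504069	A	0.600	-0.0027	0.0005	4.33E-09	-0.0024	0.0005	2.86E-07	7.54E-07	-0.0020	0.0007	4.50E-03
tertiary	15	rs4775830	rs1153855	GATM	-127414	0.167	45533344	A	0.430	-0.0017	0.0004	1.14E-06	0.0019	0.0003	4.65E-09	2.49E-07	0.0018	0.0004	2.10E-06
tertiary	20	rs75041355	rs6127099	CYP24A1	6360	0.056	52737762	A	0.034	0.0083	0.0011	3.66E-14	0.0059	0.0011	4.87E-08	1.36E-06	0.0031	0.0012	8.90E-03
fourth	2	rs2075251	rs35472707	LRP2	15877	0.016	170011458	A	0.750	-0.0028	0.0004	8.41E-12	-0.0021	0.0004	1.12E-07	1.76E-06	-0.0031	0.0004	2.80E-15
fourth	6	rs6912283	rs881858	LINC01512	-442115	0.000	43364494	A	0.560	-0.0009	0.0004	1.34E-02	-0.0018	0.0003	8.72E-08	5.50E-07	-0.0018	0.0004	4.20E-07
fourth	9	rs4745268	rs2039424	PIP5K1B	-26649	0.107	71405525	T	0.310	0.0035	0.0004	4.45E-19	0.0022	0.0004	1.00E-08	1.82E-06	0.0012	0.0004	6.00E-03
fourth	11	rs1056819	rs233438	KCNQ1	155469	0.002	2949861	T	0.200	-0.0021	0.0004	2.10E-06	-0.0023	0.0004	1.65E-07	5.51E-07	-0.0022	0.0004	9.50E-07
fourth	20	rs2585441	rs6127099	CYP24A1	6553	0.056	52737955	C	0.190	-0.0039	0.0005	6.57E-14	-0.0025	0.0005	1.45E-06	3.18E-06	-0.0026	0.0004	1.00E-08
fourth	20	rs6062357	rs2261092	ZGPAT	538806	0.001	62892739	T	0.450	0.0020	0.0004	2.19E-08	0.0019	0.0004	8.24E-08	5.50E-07	0.0013	0.0003	2.50E-04
fifth	6	rs76426793	rs12207180	SLC22A2	-66715	0.005	160566392	A	0.120	-0.0022	0.0005	4.85E-05	-0.0023	0.0005	1.29E-06	1.73E-06	-0.0049	0.0006	2.50E-16
fifth	7	rs2695565	rs2365286	LINC01006	139133	0.000	156397312	A	0.200	0.0022	0.0004	6.54E-07	0.0023	0.0004	5.27E-07	9.67E-07	0.0027	0.0004	7.00E-10
fifth	15	rs4886425	rs10851885	NRG4	-2179960	0.001	74124543	A	0.170	-0.0027	0.0005	4.26E-09	-0.0023	0.0005	4.58E-07	5.43E-07	-0.0003	0.0004	4.50E-01
sixth	7	rs6951593	rs2365286	LINC01006	12546	0.110	156270725	A	0.047	0.0060	0.0010	4.65E-10	0.0042	0.0009	3.90E-06	7.69E-06	0.0038	0.0009	1.30E-05
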