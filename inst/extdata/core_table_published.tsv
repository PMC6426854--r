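site	matrix	Alistipes	Bacteroides	Bifidobacterium	Corynebacterium 1	Lactobacillus	Ruminococcaceae UCG-005	Ruminococcaceae UCG-010	Streptococcus	U. m. of Actinobacteria class	U. m. of Clostridiaceae 1 family	U. m. of Lachnospiraceae family	U. m. of Peptostreptococcaceae family	U. m. of Ruminococcaceae family
P1	CF	4.704	3.640	0.024	NA	0.003	NA	NA	0.001	0.003	0.138	NA	0.260	8.920
P1	MIL	0.237	0.233	0.524	NA	2.354	NA	NA	0.381	2.601	0.137	NA	0.697	0.669
P1	LIT	0.207	0.308	27.007	NA	47.502	NA	NA	4.669	0.311	0.156	NA	0.468	0.168
P1	PC	0.009	0.020	0.046	NA	87.706	NA	NA	10.707	0.314	0.012	NA	0.023	0.013
P2	CF	NA	NA	0.996	NA	NA	15.502	8.951	0.065	0.008	NA	10.097	NA	NA
P2	MIL	NA	NA	0.617	NA	NA	1.576	0.266	0.099	4.563	NA	1.918	NA	NA
P2	LIT	NA	NA	26.584	NA	NA	0.990	0.358	5.349	1.286	NA	2.523	NA	NA
P2	PC	NA	NA	0.038	NA	NA	0.007	0.002	12.915	0.266	NA	0.005	NA	NA
P3	CF	NA	5.786	0.120	0.002	NA	NA	NA	NA	NA	NA	9.505	NA	NA
P3	MIL	NA	0.180	0.023	11.698	NA	NA	NA	NA	NA	NA	0.258	NA	NA
P3	LIT	NA	0.750	3.927	10.005	NA	NA	NA	NA	NA	NA	2.902	NA	NA
P3	PC	NA	0.111	0.012	0.043	NA	NA	NA	NA	NA	NA	0.016	NA	NA
RE1	CF	NA	5.089	NA	NA	0.015	NA	NA	NA	0.001	0.243	11.009	0.221	NA
RE1	MIL	NA	0.459	NA	NA	0.663	NA	NA	NA	7.883	0.220	2.242	1.001	NA
RE1	LIT	NA	4.959	NA	NA	21.203	NA	NA	NA	1.647	1.054	5.815	5.182	NA
RE1	PC	NA	0.063	NA	NA	85.654	NA	NA	NA	0.095	0.028	0.053	0.014	NA
RE2	CF	NA	NA	0.013	NA	NA	NA	NA	0.007	NA	NA	3.409	NA	NA
RE2	MIL	NA	NA	0.122	NA	NA	NA	NA	0.043	NA	NA	1.053	NA	NA
RE2	LIT	NA	NA	2.600	NA	NA	NA	NA	1.166	NA	NA	1.394	NA	NA
RE2	PC	NA	NA	0.016	NA	NA	NA	NA	6.869	NA	NA	NA	0.033	NA
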