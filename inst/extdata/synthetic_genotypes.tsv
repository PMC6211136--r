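subject_id	snp001	snp002	snp003	snp004	snp005	snp006	snp007	snp008
S0001	1	0	0	1	1	1	0	1
S0002	1	1	2	1	1	0	2	0
S0003	1	0	1	1	1	1	0	1
S0004	1	2	2	0	1	0	0	0
S0005	0	1	0	1	0	1	0	1
S0006	2	1	1	0	1	0	1	1
S0007	2	0	0	1	0	2	0	1
S0008	1	2	0	0	0	1	1	0
S0009	1	0	0	0	1	0	1	1
S0010	1	2	1	1	0	1	1	1
S0011	1	0	1	0	0	0	0	2
S0012	1	1	0	1	1	0	1	1
S0013	0	2	1	0	0	2	0	0
S0014	1	2	0	0	1	0	1	0
S0015	0	1	2	0	0	0	1	1
S0016	2	0	1	0	2	1	0	2
S0017	2	1	2	1	1	1	1	1
S0018	1	0	1	0	1	0	1	2
S0019	0	1	1	0	2	2	2	1
S0020	1	2	1	0	0	2	1	1
S0021	1	1	2	0	0	1	1	0
S0022	1	1	2	0	0	1	1	0
S0023	1	0	0	1	2	1	1	1
S0024	0	0	1	1	1	2	0	0
S0025	1	0	0	0	1	1	1	0
S0026	2	0	1	0	0	0	0	1
S0027	1	1	0	0	1	1	0	0
S0028	2	1	0	1	1	2	1	1
S0029	1	0	1	0	1	1	0	0
S0030	2	1	1	1	1	2	0	1
S0031	1	0	1	1	0	1	0	2
S0032	1	2	0	0	1	1	0	1
S0033	0	2	1	0	1	0	0	0
S0034	1	1	2	0	1	1	1	2
S0035	2	0	2	0	2	1	1	0
S0036	2	2	2	1	0	0	2	0
S0037	0	0	1	0	1	1	0	1
S0038	1	0	0	1	2	1	1	1
S0039	1	0	0	1	1	1	0	2
S0040	1	0	0	0	1	1	1	1
S0041	1	0	0	1	2	1	1	0
S0042	1	0	1	0	2	1	1	0
S0043	1	1	1	1	0	2	2	0
S0044	1	0	2	0	2	1	0	0
S0045	1	2	1	0	0	1	0	0
S0046	0	0	0	1	1	1	1	0
S0047	1	1	0	1	0	2	0	0
S0048	1	0	1	0	1	1	0	1
S0049	1	0	0	1	1	1	0	0
S0050	2	1	1	0	0	1	0	2
S0051	2	0	1	1	0	1	0	2
S0052	2	1	1	1	1	0	0	0
S0053	2	0	0	0	1	0	1	2
S0054	0	0	0	1	0	1	1	1
S0055	1	1	2	2	1	1	2	0
S0056	1	0	1	1	1	0	0	0
S0057	0	0	1	0	1	0	0	0
S0058	0	1	1	2	1	0	1	0
S0059	1	1	2	0	1	2	0	1
S0060	1	0	2	0	0	1	0	1
S0061	0	1	1	1	2	0	1	0
S0062	0	1	0	1	2	1	0	1
S0063	0	1	0	0	0	1	1	0
S0064	2	0	1	1	0	2	2	2
S0065	0	0	1	2	1	1	0	1
S0066	0	2	1	0	1	1	0	0
S0067	2	0	0	0	0	2	0	0
S0068	1	2	0	0	0	0	0	0
S0069	2	1	1	0	0	0	1	1
S0070	0	1	1	0	0	0	1	2
S0071	1	0	1	1	1	2	0	0
S0072	1	0	0	0	0	1	1	0
S0073	2	1	1	0	1	1	0	1
S0074	0	0	1	2	1	0	1	0
S0075	1	0	0	1	1	0	0	0
S0076	1	0	1	0	1	1	1	0
S0077	0	2	2	0	0	1	0	1
S0078	2	0	2	0	0	0	0	0
S0079	0	0	1	0	1	0	0	0
S0080	0	1	0	0	1	1	1	0
S0081	2	0	2	1	0	0	0	1
S0082	0	1	0	0	2	0	1	1
S0083	0	1	1	0	0	0	1	1
S0084	0	2	1	2	0	0	1	1
S0085	2	0	1	1	0	1	2	0
S0086	1	0	2	0	0	1	0	1
S0087	1	0	1	1	1	1	0	1
S0088	1	1	0	1	1	2	1	2
S0089	1	0	2	0	2	1	1	0
S0090	1	2	0	1	1	0	0	1
S0091	1	1	2	1	2	0	1	0
S0092	0	0	0	0	0	0	0	1
S0093	2	0	1	0	0	1	1	0
S0094	1	0	0	0	1	2	1	1
S0095	2	0	2	1	1	1	1	1
S0096	0	1	0	1	1	1	1	1
S0097	0	1	1	0	1	2	0	1
S0098	0	1	1	0	2	1	1	1
S0099	0	0	1	0	1	0	1	0
S0100	1	0	1	0	1	1	0	1
S0101	1	1	0	0	1	2	0	1
S0102	2	0	0	2	1	2	2	0
S0103	0	0	0	0	0	1	0	1
S0104	1	1	1	0	1	0	0	1
S0105	0	0	0	0	1	1	0	0
S0106	1	0	1	1	0	1	2	1
S0107	1	0	0	0	0	1	1	1
S0108	2	0	1	0	1	1	0	0
S0109	1	0	0	0	2	1	2	1
S0110	1	0	0	0	2	0	1	1
S0111	0	0	1	1	1	0	0	0
S0112	1	0	1	0	1	0	1	2
S0113	1	0	1	1	2	2	0	1
S0114	0	0	1	0	2	1	2	1
S0115	0	2	0	1	0	0	1	1
S0116	1	1	0	1	0	0	0	0
S0117	1	1	2	0	2	1	2	0
S0118	1	1	1	0	2	1	2	0
S0119	1	0	0	0	0	2	0	2
S0120	1	1	2	2	0	1	0	0
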