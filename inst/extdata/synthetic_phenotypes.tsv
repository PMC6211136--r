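subject_id	status	psc	female
S0001	0	0	1
S0002	1	0	1
S0003	1	0	0
S0004	1	0	1
S0005	1	1	1
S0006	0	1	1
S0007	0	1	1
S0008	1	1	1
S0009	1	0	0
S0010	1	0	1
S0011	1	1	1
S0012	0	0	1
S0013	1	0	1
S0014	1	1	1
S0015	1	0	1
S0016	0	0	1
S0017	1	1	1
S0018	1	0	1
S0019	0	0	1
S0020	1	1	0
S0021	0	0	1
S0022	1	0	1
S0023	1	0	1
S0024	0	0	1
S0025	1	0	1
S0026	0	1	1
S0027	0	0	1
S0028	0	0	1
S0029	1	1	0
S0030	0	1	0
S0031	1	0	1
S0032	0	0	1
S0033	1	1	1
S0034	1	0	1
S0035	1	0	1
S0036	0	1	1
S0037	1	0	1
S0038	1	0	1
S0039	1	0	1
S0040	1	0	1
S0041	1	0	1
S0042	0	0	0
S0043	0	0	1
S0044	1	1	1
S0045	1	1	1
S0046	0	0	1
S0047	0	0	1
S0048	0	0	1
S0049	1	1	0
S0050	1	1	1
S0051	0	0	1
S0052	1	1	1
S0053	0	1	1
S0054	0	0	1
S0055	1	1	1
S0056	1	0	0
S0057	0	0	1
S0058	1	1	1
S0059	0	0	0
S0060	0	0	1
S0061	1	0	0
S0062	0	1	1
S0063	1	0	1
S0064	1	0	1
S0065	0	0	1
S0066	0	0	1
S0067	0	0	1
S0068	1	1	1
S0069	1	0	1
S0070	0	0	0
S0071	1	1	1
S0072	0	0	1
S0073	0	0	1
S0074	1	1	1
S0075	0	0	1
S0076	1	1	1
S0077	0	0	0
S0078	0	0	1
S0079	0	0	1
S0080	1	0	1
S0081	1	0	1
S0082	0	0	1
S0083	0	0	1
S0084	0	1	1
S0085	1	0	1
S0086	1	1	1
S0087	1	1	1
S0088	1	0	1
S0089	1	0	1
S0090	0	0	1
S0091	1	0	1
S0092	1	0	1
S0093	1	0	1
S0094	1	0	1
S0095	0	0	1
S0096	1	1	1
S0097	1	0	1
S0098	0	0	1
S0099	0	0	1
S0100	1	1	1
S0101	0	0	0
S0102	1	1	1
S0103	1	0	1
S0104	1	1	0
S0105	0	0	0
S0106	0	0	1
S0107	1	1	1
S0108	1	0	1
S0109	1	0	1
S0110	1	1	0
S0111	1	1	1
S0112	0	0	1
S0113	1	1	1
S0114	0	1	1
S0115	1	1	1
S0116	0	1	1
S0117	0	0	1
S0118	0	0	1
S0119	1	0	1
S0120	0	1	1
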