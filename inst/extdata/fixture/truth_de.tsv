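protein	gene	contrast	is_de	effect
PROT0001	GENE0001	tumor_vs_normal	FALSE	0
PROT0002	GENE0002	tumor_vs_normal	FALSE	0
PROT0003	GENE0003	tumor_vs_normal	FALSE	0
PROT0004	GENE0004	tumor_vs_normal	FALSE	0
PROT0005	GENE0005	tumor_vs_normal	FALSE	0
PROT0006	GENE0006	tumor_vs_normal	FALSE	0
PROT0007	GENE0007	tumor_vs_normal	FALSE	0
PROT0008	GENE0008	tumor_vs_normal	FALSE	0
PROT0009	GENE0009	tumor_vs_normal	TRUE	1.5
PROT0010	GENE0010	tumor_vs_normal	FALSE	0
PROT0011	GENE0011	tumor_vs_normal	FALSE	0
PROT0012	GENE0012	tumor_vs_normal	TRUE	1.5
PROT0013	GENE0013	tumor_vs_normal	FALSE	0
PROT0014	GENE0014	tumor_vs_normal	FALSE	0
PROT0015	GENE0015	tumor_vs_normal	FALSE	0
PROT0016	GENE0016	tumor_vs_normal	TRUE	1.5
PROT0017	GENE0017	tumor_vs_normal	FALSE	0
PROT0018	GENE0018	tumor_vs_normal	FALSE	0
PROT0019	GENE0019	tumor_vs_normal	FALSE	0
PROT0020	GENE0020	tumor_vs_normal	TRUE	-1.5
PROT0021	GENE0021	tumor_vs_normal	FALSE	0
PROT0022	GENE0022	tumor_vs_normal	FALSE	0
PROT0023	GENE0023	tumor_vs_normal	FALSE	0
PROT0024	GENE0024	tumor_vs_normal	FALSE	0
PROT0025	GENE0025	tumor_vs_normal	FALSE	0
PROT0026	GENE0026	tumor_vs_normal	FALSE	0
PROT0027	GENE0027	tumor_vs_normal	FALSE	0
PROT0028	GENE0028	tumor_vs_normal	FALSE	0
PROT0029	GENE0029	tumor_vs_normal	TRUE	1.5
PROT0030	GENE0030	tumor_vs_normal	FALSE	0
PROT0031	GENE0031	tumor_vs_normal	FALSE	0
PROT0032	GENE0032	tumor_vs_normal	FALSE	0
PROT0033	GENE0033	tumor_vs_normal	FALSE	0
PROT0034	GENE0034	tumor_vs_normal	FALSE	0
PROT0035	GENE0035	tumor_vs_normal	FALSE	0
PROT0036	GENE0036	tumor_vs_normal	TRUE	-1.5
PROT0037	GENE0037	tumor_vs_normal	FALSE	0
PROT0038	GENE0038	tumor_vs_normal	TRUE	1.5
PROT0039	GENE0039	tumor_vs_normal	TRUE	1.5
PROT0040	GENE0040	tumor_vs_normal	FALSE	0
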