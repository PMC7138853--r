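TRUE_UP_SET	synthetic set enriched in tumor-up genes	GENE0009	GENE0012	GENE0016	GENE0029	GENE0038	GENE0039	GENE0005	GENE0015	GENE0021
TRUE_DOWN_SET	synthetic set enriched in tumor-down genes	GENE0020	GENE0036	GENE0024	GENE0023	GENE0011
RANDOM_SET_A	random background set	GENE0029	GENE0016	GENE0030	GENE0018	GENE0025	GENE0027	GENE0040	GENE0006	GENE0012	GENE0023	GENE0007	GENE0019
RANDOM_SET_B	random background set	GENE0039	GENE0038	GENE0014	GENE0029	GENE0023	GENE0030	GENE0011	GENE0013
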