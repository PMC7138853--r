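protein	plex1	plex2	plex3
PROT0001	0.096577579561183957	0.41763491278028125	0.17028617832706058
PROT0002	-0.23515168226411262	-0.14285217691640226	-0.14786320606604242
PROT0003	0.4727182559375932	0.19510456821789152	1.8865219605337224e-05
PROT0004	0.19286979171519489	0.41733313691700014	0.33686689301398987
PROT0005	0.0269281939798817	-0.33323666383436962	0.43195672289285697
PROT0006	0.082965224187438902	-0.25823777606335263	-0.3291341305217465
PROT0007	0.20378664481658124	-0.33952160425613098	-0.035195868075053052
PROT0008	0.026949865973724511	-0.43776419985071874	0.36044952027591032
PROT0009	-0.89792702494588039	0.023994765972348352	-0.14091887416989027
PROT0010	0.085464886059197817	0.195961301894757	-0.015740845481698899
PROT0011	-0.1101703928222926	0.36028961267954823	-0.025832189471126865
PROT0012	0.055569169459682793	0.31342532615031754	-0.26630370537192943
PROT0013	0.17454711820965199	-0.30096259405195441	-0.13340520146542142
PROT0014	0.41992104818780346	0.55454457050182393	-0.0088334637264714435
PROT0015	-0.2181876178423395	-0.20003202262734515	-0.12416065471737706
PROT0016	0.39076278961324312	0.031654143736820829	0.33401580701046091
PROT0017	0.10075443592562233	-0.1266767645606568	-0.14429785249619456
PROT0018	0.31155182960928635	-0.036705051586491393	-0.12995070978021869
PROT0019	0.27621857048719389	0.056457910350449364	0.20905877296563083
PROT0020	0.21626344886005874	0.035748287399101915	-0.31691052395127245
PROT0021	-0.31293568157035651	-0.0075277652602208627	-0.012209542545364478
PROT0022	-0.027055915983212005	0.032421818382609768	-0.46546344670427686
PROT0023	0.18705544859986306	-0.14563057075400029	0.35015086477070451
PROT0024	-0.28605700733170319	-0.15126513920637105	-0.0820937104122242
PROT0025	-0.16284864437215699	-0.49832972397444358	-0.14035359740167605
PROT0026	0.17429894930450474	-0.11470011806214538	-0.37147569839586431
PROT0027	0.23045362135037728	-0.15379507736334011	-0.0023286101331979887
PROT0028	0.13913027656205015	0.81056730010343947	-0.24008465338549786
PROT0029	-0.26573288922290383	-0.40863486935691556	-0.16004769898513094
PROT0030	-0.32993426959435668	0.041176865567582079	0.38630257367537657
PROT0031	0.45381210294147845	-0.44808752019488712	-0.052657761072638219
PROT0032	0.077376431259609246	-0.44113072243103896	-0.32153471524520277
PROT0033	0.026532068747875906	0.037410715859102037	0.048962064740214695
PROT0034	-0.036268961261726837	-0.29899174046521121	-0.10882152468838495
PROT0035	-0.35829866854815845	-0.00054678429141245875	0.17700406439620162
PROT0036	0.18359906941211607	-0.12847766442774458	0.429726578319297
PROT0037	-0.065141953723956245	-0.1841014819348486	-0.29780775333284781
PROT0038	-0.054827011899576519	-0.60740335362573228	0.13639508927408478
PROT0039	0.280003898571348	-0.3674243851079958	0.025469417603546186
PROT0040	0.24653193315247474	0.053854932335381377	0.26866967467936342
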