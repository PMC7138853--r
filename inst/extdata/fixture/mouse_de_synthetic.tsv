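gene	log2fc	p	q
Gene0001	-0.012055	0.31325454	0.87108287
Gene0002	0.031515	0.46525434	0.87108287
Gene0003	0.087691	0.7770844	0.9195546
Gene0004	0.010544	0.311745	0.87108287
Gene0005	0.074939	0.6218318	0.87108287
Gene0006	-0.061352	0.35416762	0.87108287
Gene0007	-0.021224	0.94858633	0.96354316
Gene0008	0.096338	0.84180726	0.9353414
Gene0009	1.51486	0.00027518	0.00372947
Gene0010	0.039597	0.52991166	0.87108287
Gene0011	-0.077548	0.41680149	0.87108287
Gene0012	1.404646	0.00060198	0.00391829
Gene0013	0.02806	0.48575676	0.87108287
Gene0014	0.018222	0.68230868	0.90974491
Gene0015	0.193613	0.74308086	0.9195546
Gene0016	1.522053	0.0006857	0.00391829
Gene0017	-0.102136	0.93361026	0.96354316
Gene0018	0.017446	0.39011401	0.87108287
Gene0019	0.068106	0.59100015	0.87108287
Gene0020	-1.533419	0.0001399	0.00372947
Gene0021	0.122071	0.22984971	0.87108287
Gene0022	-0.0803	0.54630646	0.87108287
Gene0023	0.004581	0.63153508	0.87108287
Gene0024	-0.004571	0.40864778	0.87108287
Gene0025	-0.021507	0.78162141	0.9195546
Gene0026	0.166799	0.45291165	0.87108287
Gene0027	-0.066238	0.5188378	0.87108287
Gene0028	0.017463	0.60525001	0.87108287
Gene0029	1.344719	0.00054246	0.00391829
Gene0030	0.123487	0.33314891	0.87108287
Gene0031	0.066006	0.31668574	0.87108287
Gene0032	0.055189	0.90466384	0.96354316
Gene0033	-0.129391	0.48331078	0.87108287
Gene0034	0.117987	0.71395242	0.9195546
Gene0035	0.11705	0.54252154	0.87108287
Gene0036	-1.547636	0.00089095	0.00445475
Gene0037	-0.086351	0.96354316	0.96354316
Gene0038	1.731895	0.00027971	0.00372947
Gene0039	1.641685	0.00066653	0.00391829
Gene0040	-0.011639	0.82560816	0.9353414
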