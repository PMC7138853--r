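plex_id	channel	sample_id	is_reference
plex1	126	normal_01	FALSE
plex1	127N	normal_04	FALSE
plex1	127C	normal_07	FALSE
plex1	128N	tnbc_01	FALSE
plex1	128C	tnbc_04	FALSE
plex1	129N	spindle_01	FALSE
plex1	129C	spindle_04	FALSE
plex1	130N	squamous_03	FALSE
plex1	130C	sarcomatoid_02	FALSE
plex1	131	plex1_ref	TRUE
plex2	126	normal_02	FALSE
plex2	127N	normal_05	FALSE
plex2	127C	normal_08	FALSE
plex2	128N	tnbc_02	FALSE
plex2	128C	tnbc_05	FALSE
plex2	129N	spindle_02	FALSE
plex2	129C	squamous_01	FALSE
plex2	130N	squamous_04	FALSE
plex2	130C	sarcomatoid_03	FALSE
plex2	131	plex2_ref	TRUE
plex3	126	normal_03	FALSE
plex3	127N	normal_06	FALSE
plex3	127C	normal_09	FALSE
plex3	128N	tnbc_03	FALSE
plex3	128C	tnbc_06	FALSE
plex3	129N	spindle_03	FALSE
plex3	129C	squamous_02	FALSE
plex3	130N	sarcomatoid_01	FALSE
plex3	130C	sarcomatoid_04	FALSE
plex3	131	plex3_ref	TRUE
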