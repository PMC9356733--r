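node_id	network	excluded
roi001	DMN	0
roi002	DMN	0
roi003	DMN	0
roi004	DMN	0
roi005	DMN	0
roi006	DMN	0
roi007	DMN	0
roi008	DMN	0
roi009	DMN	0
roi010	DMN	0
roi011	DMN	0
roi012	DMN	0
roi013	DMN	0
roi014	DMN	0
roi015	DMN	0
roi016	DMN	0
roi017	DMN	0
roi018	DMN	0
roi019	DMN	0
roi020	DMN	0
roi021	DMN	0
roi022	DMN	0
roi023	DMN	0
roi024	DMN	0
roi025	DMN	0
roi026	DMN	0
roi027	DMN	0
roi028	DMN	0
roi029	DMN	0
roi030	DMN	0
roi031	DMN	0
roi032	DMN	0
roi033	DMN	0
roi034	DMN	0
roi035	DMN	0
roi036	DMN	0
roi037	DMN	0
roi038	DMN	0
roi039	MFN	0
roi040	MFN	0
roi041	MFN	0
roi042	MFN	0
roi043	MFN	0
roi044	MFN	0
roi045	MFN	0
roi046	MFN	0
roi047	MFN	0
roi048	MFN	0
roi049	MFN	0
roi050	MFN	0
roi051	MFN	0
roi052	MFN	0
roi053	MFN	0
roi054	MFN	0
roi055	MFN	0
roi056	MFN	0
roi057	MFN	0
roi058	MFN	0
roi059	FPN	0
roi060	FPN	0
roi061	FPN	0
roi062	FPN	0
roi063	FPN	0
roi064	FPN	0
roi065	FPN	0
roi066	FPN	0
roi067	FPN	0
roi068	FPN	0
roi069	FPN	0
roi070	FPN	0
roi071	FPN	0
roi072	FPN	0
roi073	FPN	0
roi074	FPN	0
roi075	FPN	0
roi076	FPN	0
roi077	FPN	0
roi078	FPN	0
roi079	FPN	0
roi080	FPN	0
roi081	FPN	0
roi082	FPN	0
roi083	FPN	0
roi084	FPN	0
roi085	FPN	0
roi086	FPN	0
roi087	limbic	0
roi088	limbic	0
roi089	limbic	0
roi090	limbic	0
roi091	limbic	0
roi092	limbic	0
roi093	limbic	0
roi094	limbic	0
roi095	limbic	0
roi096	limbic	0
roi097	limbic	0
roi098	limbic	0
roi099	limbic	0
roi100	limbic	0
roi101	limbic	0
roi102	limbic	0
roi103	limbic	0
roi104	limbic	0
roi105	limbic	0
roi106	limbic	0
roi107	limbic	0
roi108	limbic	0
roi109	limbic	0
roi110	limbic	0
roi111	motor	0
roi112	motor	0
roi113	motor	0
roi114	motor	0
roi115	motor	0
roi116	motor	0
roi117	motor	0
roi118	motor	0
roi119	motor	0
roi120	motor	0
roi121	motor	0
roi122	motor	0
roi123	motor	0
roi124	motor	0
roi125	motor	0
roi126	motor	0
roi127	motor	0
roi128	motor	0
roi129	motor	0
roi130	motor	0
roi131	motor	0
roi132	motor	0
roi133	motor	0
roi134	motor	0
roi135	motor	0
roi136	motor	0
roi137	motor	0
roi138	visual1	0
roi139	visual1	0
roi140	visual1	0
roi141	visual1	0
roi142	visual1	0
roi143	visual1	0
roi144	visual1	0
roi145	visual1	0
roi146	visual1	0
roi147	visual1	0
roi148	visual1	0
roi149	visual1	0
roi150	visual1	0
roi151	visual1	0
roi152	visual2	0
roi153	visual2	0
roi154	visual2	0
roi155	visual2	0
roi156	visual2	0
roi157	visual2	0
roi158	visual2	0
roi159	visual2	0
roi160	visual2	0
roi161	visual2	0
roi162	visual2	0
roi163	visual2	0
roi164	visual2	0
roi165	visual2	0
roi166	visual2	0
roi167	visual2	0
roi168	visual_assoc	0
roi169	visual_assoc	0
roi170	visual_assoc	0
roi171	visual_assoc	0
roi172	visual_assoc	0
roi173	visual_assoc	0
roi174	visual_assoc	0
roi175	visual_assoc	0
roi176	visual_assoc	0
roi177	visual_assoc	0
roi178	visual_assoc	0
roi179	visual_assoc	0
roi180	visual_assoc	0
roi181	visual_assoc	0
roi182	visual_assoc	0
roi183	visual_assoc	0
roi184	visual_assoc	0
roi185	visual_assoc	0
roi186	visual_assoc	0
roi187	visual_assoc	0
roi188	visual_assoc	0
roi189	visual_assoc	0
roi190	visual_assoc	0
roi191	visual_assoc	0
roi192	BGN	0
roi193	BGN	0
roi194	BGN	0
roi195	BGN	0
roi196	BGN	0
roi197	BGN	0
roi198	BGN	0
roi199	BGN	0
roi200	BGN	0
roi201	BGN	0
roi202	BGN	0
roi203	BGN	0
roi204	BGN	0
roi205	BGN	0
roi206	BGN	0
roi207	BGN	0
roi208	BGN	0
roi209	BGN	0
roi210	BGN	0
roi211	BGN	0
roi212	BGN	0
roi213	BGN	0
roi214	BGN	0
roi215	BGN	0
roi216	BGN	0
roi217	BGN	0
roi218	BGN	0
roi219	BGN	0
roi220	cerebellum	1
roi221	cerebellum	1
roi222	cerebellum	1
roi223	cerebellum	1
roi224	cerebellum	1
roi225	cerebellum	1
roi226	cerebellum	1
roi227	cerebellum	1
roi228	cerebellum	1
roi229	cerebellum	1
roi230	cerebellum	1
roi231	cerebellum	1
roi232	cerebellum	1
roi233	cerebellum	1
roi234	cerebellum	1
roi235	cerebellum	1
roi236	cerebellum	1
roi237	cerebellum	1
roi238	cerebellum	1
roi239	cerebellum	1
roi240	cerebellum	1
roi241	cerebellum	1
roi242	cerebellum	1
roi243	cerebellum	1
roi244	cerebellum	1
roi245	cerebellum	1
roi246	cerebellum	1
roi247	cerebellum	1
roi248	cerebellum	1
roi249	cerebellum	1
roi250	cerebellum	1
roi251	cerebellum	1
roi252	cerebellum	1
roi253	cerebellum	1
roi254	cerebellum	1
roi255	cerebellum	1
roi256	cerebellum	1
roi257	cerebellum	1
roi258	cerebellum	1
roi259	cerebellum	1
roi260	cerebellum	1
roi261	cerebellum	1
roi262	cerebellum	1
roi263	cerebellum	1
roi264	cerebellum	1
roi265	cerebellum	1
roi266	cerebellum	1
roi267	cerebellum	1
roi268	cerebellum	1
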