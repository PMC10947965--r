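id	name	lobe	hemisphere	in_abeta_set	in_tau_set
1	L bankssts	temporal	L	TRUE	FALSE
2	L caudal anterior cingulate	frontal	L	TRUE	FALSE
3	L caudal middle frontal	frontal	L	TRUE	FALSE
4	L cuneus	occipital	L	FALSE	FALSE
5	L entorhinal	temporal	L	FALSE	TRUE
6	L fusiform	temporal	L	FALSE	TRUE
7	L inferior parietal	parietal	L	TRUE	FALSE
8	L inferior temporal	temporal	L	TRUE	TRUE
9	L isthmus cingulate	parietal	L	TRUE	FALSE
10	L lateral occipital	occipital	L	FALSE	FALSE
11	L lateral orbitofrontal	frontal	L	TRUE	FALSE
12	L lingual	occipital	L	FALSE	FALSE
13	L medial orbitofrontal	frontal	L	FALSE	FALSE
14	L middle temporal	temporal	L	TRUE	TRUE
15	L parahippocampal	temporal	L	FALSE	TRUE
16	L paracentral	frontal	L	FALSE	FALSE
17	L pars opercularis	frontal	L	FALSE	FALSE
18	L pars orbitalis	frontal	L	TRUE	FALSE
19	L pars triangularis	frontal	L	TRUE	FALSE
20	L pericalcarine	occipital	L	FALSE	FALSE
21	L postcentral	parietal	L	FALSE	FALSE
22	L posterior cingulate	parietal	L	TRUE	FALSE
23	L precentral	frontal	L	FALSE	FALSE
24	L precuneus	parietal	L	TRUE	FALSE
25	L rostral anterior cingulate	frontal	L	TRUE	FALSE
26	L rostral middle frontal	frontal	L	TRUE	FALSE
27	L superior frontal	frontal	L	TRUE	FALSE
28	L superior parietal	parietal	L	TRUE	FALSE
29	L superior temporal	temporal	L	TRUE	FALSE
30	L supramarginal	parietal	L	TRUE	FALSE
31	L frontal pole	frontal	L	TRUE	FALSE
32	L temporal pole	temporal	L	FALSE	FALSE
33	L transverse temporal	temporal	L	FALSE	FALSE
34	L insula	other	L	TRUE	FALSE
35	L amygdala	temporal	L	FALSE	TRUE
36	L anterior ventral striatum	other	L	TRUE	FALSE
101	R bankssts	temporal	R	TRUE	FALSE
102	R caudal anterior cingulate	frontal	R	TRUE	FALSE
103	R caudal middle frontal	frontal	R	TRUE	FALSE
104	R cuneus	occipital	R	FALSE	FALSE
105	R entorhinal	temporal	R	FALSE	TRUE
106	R fusiform	temporal	R	FALSE	TRUE
107	R inferior parietal	parietal	R	TRUE	FALSE
108	R inferior temporal	temporal	R	TRUE	TRUE
109	R isthmus cingulate	parietal	R	TRUE	FALSE
110	R lateral occipital	occipital	R	FALSE	FALSE
111	R lateral orbitofrontal	frontal	R	TRUE	FALSE
112	R lingual	occipital	R	FALSE	FALSE
113	R medial orbitofrontal	frontal	R	FALSE	FALSE
114	R middle temporal	temporal	R	TRUE	TRUE
115	R parahippocampal	temporal	R	FALSE	TRUE
116	R paracentral	frontal	R	FALSE	FALSE
117	R pars opercularis	frontal	R	FALSE	FALSE
118	R pars orbitalis	frontal	R	TRUE	FALSE
119	R pars triangularis	frontal	R	TRUE	FALSE
120	R pericalcarine	occipital	R	FALSE	FALSE
121	R postcentral	parietal	R	FALSE	FALSE
122	R posterior cingulate	parietal	R	TRUE	FALSE
123	R precentral	frontal	R	FALSE	FALSE
124	R precuneus	parietal	R	TRUE	FALSE
125	R rostral anterior cingulate	frontal	R	TRUE	FALSE
126	R rostral middle frontal	frontal	R	TRUE	FALSE
127	R superior frontal	frontal	R	TRUE	FALSE
128	R superior parietal	parietal	R	TRUE	FALSE
129	R superior temporal	temporal	R	TRUE	FALSE
130	R supramarginal	parietal	R	TRUE	FALSE
131	R frontal pole	frontal	R	TRUE	FALSE
132	R temporal pole	temporal	R	FALSE	FALSE
133	R transverse temporal	temporal	R	FALSE	FALSE
134	R insula	other	R	TRUE	FALSE
135	R amygdala	temporal	R	FALSE	TRUE
136	R anterior ventral striatum	other	R	TRUE	FALSE
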