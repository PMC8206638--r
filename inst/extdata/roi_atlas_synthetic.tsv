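roi	structure	hemisphere
cingulate_ant_L	Cingulate	L
cingulate_ant_R	Cingulate	R
ofc_medial_L	OrbitoFrontal	L
ofc_medial_R	OrbitoFrontal	R
ofc_lateral_L	OrbitoFrontal	L
ofc_lateral_R	OrbitoFrontal	R
principal_sulcus_L	PrincipalSulcus	L
principal_sulcus_R	PrincipalSulcus	R
accumbens_L	Accumbens	L
accumbens_R	Accumbens	R
caudate_head_L	Caudate	L
caudate_head_R	Caudate	R
caudate_body_L	Caudate	L
caudate_body_R	Caudate	R
putamen_head_L	Putamen	L
putamen_head_R	Putamen	R
parietal_sup_L	Parietal	L
parietal_sup_R	Parietal	R
parietal_inf_L	Parietal	L
parietal_inf_R	Parietal	R
precuneus_L	Precuneus	L
precuneus_R	Precuneus	R
amygdala_lat_L	Amygdala	L
amygdala_lat_R	Amygdala	R
amygdala_med_L	Amygdala	L
amygdala_med_R	Amygdala	R
hippocampus_ant_L	Hippocampus	L
hippocampus_ant_R	Hippocampus	R
hippocampus_med_L	Hippocampus	L
hippocampus_med_R	Hippocampus	R
hippocampus_post_L	Hippocampus	L
hippocampus_post_R	Hippocampus	R
cerebellum_ant_L	Cerebellum	L
cerebellum_ant_R	Cerebellum	R
cerebellum_post_L	Cerebellum	L
cerebellum_post_R	Cerebellum	R
vermis	Cerebellum	M
thalamus_L	Thalamus	L
thalamus_R	Thalamus	R
insula_ant_L	Insula	L
insula_ant_R	Insula	R
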