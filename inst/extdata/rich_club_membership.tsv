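region	baseline	free_access
Putamen	5	4
Hippocampus	5	5
Thalamus	5	3
Insula	5	2
Cerebellum	5	3
Parietal	4	3
Amygdala	4	5
OrbitoFrontal	4	3
Caudate	3	3
Precuneus	3	2
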