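region	baseline	free_access
Parietal	3	0
Thalamus	4	2
Precuneus	2	1
Cerebellum	4	2
Amygdala	2	2
Hippocampus	2	4
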