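subject_id	free_access_g_per_kg
1	3.8
2	4.4
3	5.4
4	5.5
5	3.3
6	5.9
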