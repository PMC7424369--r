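table_id	split_factor	split_level1	split_level2	test_factor	test_level1	test_level2	a	b	c	d
smoking_sex	smoking	smoker	nonsmoker	sex	male	female	31	18	33	11
smoking_race	smoking	smoker	nonsmoker	race	white	black	14	35	20	24
sex_race	sex	male	female	race	white	black	25	9	39	20
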