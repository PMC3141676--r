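# Published pairwise overlap counts between the three libraries:
# unique tag counts per library, shared unique tags, redundant read
# totals and shared redundant reads. Unions and percentages are
# recomputed by overlap_table().
pair	lib_a	lib_b	unique_a	unique_b	common_unique	total_a	total_b	common_total
PT1_&_PT2	PT1	PT2	718770	596498	173647	8924476	5609466	13293850
PT2_&_PT3	PT2	PT3	596498	672323	169588	5609466	6982282	11460968
PT1_&_PT3	PT1	PT3	718770	672323	200334	8924476	6982282	14690632
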