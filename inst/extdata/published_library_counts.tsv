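# Published per-library read counts: three small RNA libraries from
# P. tricornutum grown under normal (PT1), nitrogen-limited (PT2) and
# silicon-limited (PT3) conditions. Counts after adapter removal and
# length filtering at 18 nt; genome/chloroplast matches are exact hits.
sample	total	unique	genome_total	genome_unique	chloroplast_total	chloroplast_unique	singleton
PT1	8924476	718770	4105629	221523	3076974	68048	521761
PT2	5609466	596498	2492000	262038	1503395	43151	441959
PT3	6982282	672323	2908127	250371	2410100	55321	491748
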