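# Literal transcription of the published intermittent-claudication score
# system (points per predictor bin, then score-to-risk conversion), kept as
# a change-detection reference for the builtin fixture.
predictor	range_or_level	points
Sex	male	3
Sex	female	0
Age	45-49	0
Age	50-54	1
Age	55-59	2
Age	60-64	3
Age	65-69	4
Age	70-74	5
Age	75-79	6
Age	80-84	7
Cholesterol, mg/dL	< 170	0
Cholesterol, mg/dL	170-209	1
Cholesterol, mg/dL	210-249	2
Cholesterol, mg/dL	250-289	3
Cholesterol, mg/dL	> 289	4
Blood pressure	normal	0
Blood pressure	high normal	1
Blood pressure	stage 1	2
Blood pressure	stage 2+	4
Cigarettes/d, n	0	0
Cigarettes/d, n	1-5	1
Cigarettes/d, n	6-10	2
Cigarettes/d, n	11-20	3
Cigarettes/d, n	> 20	4
Diabetes	no	0
Diabetes	yes	5
Coronary heart disease	no	0
Coronary heart disease	yes	5
score	estimate
< 10	< 1%
10-12	1%
13-15	2%
16-17	3%
18	4%
19	5%
20	6%
21	7%
22	8%
23	10%
24	11%
25	13%
26	16%
27	18%
28	21%
29	24%
30	28%
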