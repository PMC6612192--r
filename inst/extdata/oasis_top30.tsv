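# Top 30 keywords of the OASIS Korean-medicine corpus (1963-2018) by number
# of articles containing the keyword, as published for the 29,876-article
# study. Keywords are shown in readable form; normalize_keyword() gives the
# token used in analysis.
rank	keyword	frequency
1	acupuncture	1153
2	korean medicine	870
3	sasang constitution	671
4	herbal medicine	648
5	obesity	497
6	oriental medicine	440
7	stroke	378
8	anti-inflammation	377
9	apoptosis	374
10	no	369
11	antioxidative activity	325
12	cytokine	318
13	atopic dermatitis	299
14	electroacupuncture	293
15	visual analogue scale	289
16	moxibustion	284
17	heart rate variability	271
18	dongeuibogam	253
19	herbal acupuncture	246
20	antioxidant	235
21	tnf-α	223
22	low back pain	211
23	pharmacopuncture	209
24	bell's palsy	202
25	hyperlipidemia	194
26	oriental medical therapy	175
27	diabetes	173
28	toxicity	171
29	cox-2	167
30	inflammation	166
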