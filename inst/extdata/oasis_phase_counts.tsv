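# Per-phase appearance frequencies for selected keywords of the OASIS
# Korean-medicine corpus, as published for the six chronological phases
# 1963-1978, 1979-1986, 1987-1994, 1995-2001, 2002-2012, 2013-2018.
# Only rows whose published digits admit a single parse consistent with the
# keyword's total frequency and the narrative are included here.
# article_totals: 643 498 1889 5758 15921 5167
keyword	p1963_1978	p1979_1986	p1987_1994	p1995_2001	p2002_2012	p2013_2018
acupuncture	6	10	29	140	653	315
oriental medicine	8	7	17	74	299	35
korean medicine	0	0	0	4	314	552
pharmacopuncture	0	0	0	0	89	120
sasang constitution	5	0	17	63	413	173
anti-inflammation	0	12	10	17	214	124
gastric cancer	0	0	0	2	6	8
colorectal cancer	0	0	0	3	4	5
systematic review	0	0	0	0	47	73
case report	0	0	0	0	15	54
clinical practice guideline	0	0	0	0	5	42
integrative medicine	0	0	0	0	8	27
meta-analysis	0	0	0	0	7	27
toxicity test	0	0	0	0	8	21
mibyeong	0	0	0	0	0	14
systems biology	0	0	0	0	0	11
korean medicine hospital	0	0	0	0	0	15
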