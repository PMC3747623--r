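# Published genomic word over/under-representation scores, C = (Obs-Exp)/Exp * 100%,
# for H. sapiens and D. melanogaster (transcribed from the printed table; the
# expectation is based on the frequencies of the word's subwords).
word	c_sapiens	c_melanogaster	group
CG	-76.37	-5.93	human_bias_context_words
ATAG	-0.79	4.38	human_bias_context_words
ATTG	-7.07	-2.35	human_bias_context_words
ACAA	1.62	3.75	human_bias_context_words
TG	20.10	10.67	derived_from_human_bias_contexts
ACAG	1.51	-4.94	derived_from_human_bias_contexts
ACTG	-2.07	-0.46	derived_from_human_bias_contexts
CCAA	-6.17	-1.61	derived_from_human_bias_contexts
CCAC	0.19	1.52	fly_bias_context_words
CACC	1.18	-4.24	fly_bias_context_words
CCCA	5.63	0.09	fly_bias_context_words
GCCA	-2.77	3.63	fly_bias_context_words
ACC	2.28	-2.39	fly_bias_context_words
CCA	14.82	9.90	fly_bias_context_words
CCCC	-5.10	2.19	derived_from_fly_bias_contexts
GCCC	1.66	-1.41	derived_from_fly_bias_contexts
CCC	-12.66	-7.78	derived_from_fly_bias_contexts
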