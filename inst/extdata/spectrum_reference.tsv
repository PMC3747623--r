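# Published single-nucleotide mutation spectrum fractions (transcribed from
# the printed comparative table; decimal commas converted to points).
species	substitution	fraction
melanogaster	A>C	0.044
melanogaster	T>G	0.047
melanogaster	C>G	0.047
melanogaster	G>C	0.048
melanogaster	A>T	0.057
melanogaster	T>A	0.058
melanogaster	A>G	0.063
melanogaster	T>C	0.064
melanogaster	G>T	0.118
melanogaster	C>A	0.121
melanogaster	C>T	0.166
melanogaster	G>A	0.167
sapiens	A>T	0.031
sapiens	T>A	0.031
sapiens	A>C	0.037
sapiens	T>G	0.038
sapiens	C>G	0.051
sapiens	G>C	0.051
sapiens	G>T	0.058
sapiens	C>A	0.058
sapiens	T>C	0.118
sapiens	A>G	0.118
sapiens	C>T	0.204
sapiens	G>A	0.204
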