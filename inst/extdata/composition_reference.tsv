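# Published D. melanogaster nucleotide composition: complete alignments vs
# conserved regions, with the printed percent-difference column.
nucleotide	frac_all	frac_conserved	difference_pct
a	0.2979	0.2901	2.6
t	0.2978	0.2899	2.7
c	0.2022	0.2100	-3.9
g	0.2021	0.2100	-3.9
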