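# Contexts reported as differentially mutable between the human germline and
# D. melanogaster (qualitative; the full per-context human table is external
# reference data and is consumed, never recomputed here).
context	elevated_in	note
{C>T|1,CG}	sapiens	CpG deamination under germline methylation; absent in the fly
{T>C|2,ATTG}	sapiens	hypermutable in the human germline, not in the fly
{T>C|2,ATAG}	sapiens	hypermutable in the human germline, not in the fly
{A>C|1,ACAA}	sapiens	hypermutable in the human germline, not in the fly
{A>C|3,CCA}	melanogaster	highest minimal contrast in the fly
{A>C|2,CACC}	melanogaster	highest minimal contrast in the fly
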