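gene_a	gene_b	evidence
G00002	G00021	experimental
G00003	G00023	experimental
G00005	G00017	experimental
G00007	G00011	experimental
G00007	G00013	experimental
G00007	G00020	experimental
G00009	G00025	experimental
G00010	G00030	experimental
G00013	G00034	experimental
G00014	G00018	experimental
G00018	G00032	predicted
G00019	G00026	experimental
G00021	G00029	experimental
G00024	G00027	experimental
G00031	G00034	experimental
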