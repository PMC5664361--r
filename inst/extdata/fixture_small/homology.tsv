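gene_a	gene_b	pct_identity	confidence	relation
G00001	G00002	77.6125278288964	high	paralog
G00001	G00003	92.7081511670258	high	ortholog
G00001	G00004	81.885491523426	high	ortholog
G00002	G00003	73.1147757091094	high	ortholog
G00002	G00004	90.6575696833897	high	ortholog
G00003	G00004	69.9255518976133	high	ortholog
G00006	G00007	92.403275873512	high	ortholog
G00006	G00013	24.4840389769524	high	ortholog
G00008	G00009	89.4625503604766	high	ortholog
G00008	G00010	62.02218158287	high	ortholog
G00008	G00011	91.0854758194182	high	ortholog
G00009	G00010	91.441742554307	high	ortholog
G00009	G00011	74.6298774157185	high	ortholog
G00010	G00011	81.7949412378948	high	paralog
G00012	G00013	94.2044802953023	high	ortholog
G00014	G00015	86.0153533727862	high	paralog
G00014	G00016	61.8260124314111	high	ortholog
G00015	G00016	60.6583442969713	high	ortholog
G00017	G00018	81.00479311659	high	paralog
G00017	G00019	63.9676617237274	high	ortholog
G00018	G00019	73.2711014780216	high	ortholog
G00020	G00021	78.0745002173353	high	paralog
G00020	G00022	78.1032993656117	high	ortholog
G00020	G00023	71.9209147931542	high	ortholog
G00021	G00022	70.7933016237803	high	ortholog
G00021	G00023	87.341535766609	high	ortholog
G00022	G00023	63.1090182438493	high	ortholog
G00026	G00027	83.7843865295872	high	paralog
G00028	G00029	74.9172345339321	high	ortholog
G00028	G00030	91.3476095127407	high	ortholog
G00029	G00030	61.3377779698931	high	ortholog
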