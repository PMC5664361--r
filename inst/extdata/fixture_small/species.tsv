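species_id	kegg_flag
SP01	1
SP02	1
SP03	1
SP04	1
SP05	1
SP06	0
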