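map_id	class_id	secondary
M0101	C01	FALSE
M0102	C01	FALSE
M0201	C02	FALSE
M0202	C02	FALSE
M0301	C03	TRUE
M0302	C03	TRUE
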