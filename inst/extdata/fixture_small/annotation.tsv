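gene_id	species	ec	maps	classes
G00001	SP02	1.1.1.1	M0101	C01
G00002	SP02	1.1.1.1	M0101	C01
G00003	SP04	1.1.1.1	M0101	C01
G00004	SP06	1.1.1.1	M0101	C01
G00005	SP05	1.1.1.2	M0202;M0301;M0302	C02;C03
G00006	SP04	1.1.1.3	M0101;M0302	C01;C03
G00007	SP06	1.1.1.3	M0101;M0302	C01;C03
G00008	SP04	1.1.1.4	M0301	C03
G00009	SP05	1.1.1.4	M0301	C03
G00010	SP06	1.1.1.4	M0301	C03
G00011	SP06	1.1.1.4	M0301	C03
G00012	SP04	1.1.1.5	M0202	C02
G00013	SP05	1.1.1.5	M0202	C02
G00014	SP01	1.1.1.6	M0101;M0102	C01
G00015	SP01	1.1.1.6	M0101;M0102	C01
G00016	SP06	1.1.1.6	M0101;M0102	C01
G00017	SP02	1.1.1.7	M0202;M0301;M0302	C02;C03
G00018	SP02	1.1.1.7	M0202;M0301;M0302	C02;C03
G00019	SP05	1.1.1.7	M0202;M0301;M0302	C02;C03
G00020	SP02	1.1.1.8	M0201;M0302	C02;C03
G00021	SP02	1.1.1.8	M0201;M0302	C02;C03
G00022	SP04	1.1.1.8	M0201;M0302	C02;C03
G00023	SP06	1.1.1.8	M0201;M0302	C02;C03
G00024	SP05	1.1.1.9	M0102;M0202;M0301	C01;C02;C03
G00025	SP05	1.1.1.10	M0202;M0301	C02;C03
G00026	SP05	1.1.1.11	M0101;M0301	C01;C03
G00027	SP05	1.1.1.11	M0101;M0301	C01;C03
G00028	SP02	1.1.1.12	M0102;M0301;M0302	C01;C03
G00029	SP04	1.1.1.12	M0102;M0301;M0302	C01;C03
G00030	SP06	1.1.1.12	M0102;M0301;M0302	C01;C03
G00031	SP04	1.1.1.13	M0302	C03
G00032	SP03	1.1.1.14	M0102;M0201;M0301	C01;C02;C03
G00033	SP05	1.1.1.15	M0102;M0202;M0302	C01;C02;C03
G00034	SP04	1.1.1.16	M0101;M0102;M0202	C01;C02
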