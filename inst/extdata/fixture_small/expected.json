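{
  "families": [
    ["G00001", "G00002", "G00003", "G00004"],
    "G00005",
    ["G00006", "G00007"],
    ["G00008", "G00009", "G00010", "G00011"],
    ["G00012", "G00013"],
    ["G00014", "G00015", "G00016"],
    ["G00017", "G00018", "G00019"],
    ["G00020", "G00021", "G00022", "G00023"],
    "G00024",
    "G00025",
    ["G00026", "G00027"],
    ["G00028", "G00029", "G00030"],
    "G00031",
    "G00032",
    "G00033",
    "G00034"
  ],
  "profiles": {
    "G00001": "010101",
    "G00005": "000010",
    "G00006": "000101",
    "G00008": "000111",
    "G00012": "000110",
    "G00014": "100001",
    "G00017": "010010",
    "G00020": "010101",
    "G00024": "000010",
    "G00025": "000010",
    "G00026": "000010",
    "G00028": "010101",
    "G00031": "000100",
    "G00032": "001000",
    "G00033": "000010",
    "G00034": "000100"
  },
  "enrichment_map": {
    "M0101": {
      "n_f": 5,
      "f_pw": 0,
      "f_all": 0.107692307692308,
      "enrichment": 0
    },
    "M0102": {
      "n_f": 6,
      "f_pw": 0.0666666666666667,
      "f_all": 0.133333333333333,
      "enrichment": 0.5
    },
    "M0201": {
      "n_f": 2,
      "f_pw": 0,
      "f_all": 0.0689655172413793,
      "enrichment": 0
    },
    "M0202": {
      "n_f": 7,
      "f_pw": 0.285714285714286,
      "f_all": 0.130952380952381,
      "enrichment": 2.18181818181818
    },
    "M0301": {
      "n_f": 1,
      "f_pw": null,
      "f_all": 0,
      "enrichment": null
    },
    "M0302": {
      "n_f": 1,
      "f_pw": null,
      "f_all": 0.0666666666666667,
      "enrichment": null
    }
  }
}
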