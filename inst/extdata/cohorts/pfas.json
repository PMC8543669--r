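{
  "group": "PFAS",
  "n": 10,
  "p": {
    "A": [0.50575032192486, 0.49424967807514, 0, 0],
    "B": [0.500633499822573, 0.385941832171033, 0.113424668006395, 0],
    "C": [0.789986728563742, 0.210013271436258, 0, 0],
    "D": [0.242478032760749, 0.250037466367166, 0.331727597442562, 0.175756903429523]
  },
  "dependence": 0.17357618036047,
  "seed": null
}
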