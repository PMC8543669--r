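{
  "group": "control",
  "n": 65,
  "p": {
    "A": [0.941676071434223, 0.0583239285657774, 0, 0],
    "B": [0.965215874601537, 0.0347841253984625, 0, 0],
    "C": [0.974218579424932, 0.0257814205750685, 0, 0],
    "D": [0.896893726390718, 0.0844931666293093, 0.0186131069799727, 0]
  },
  "dependence": 0,
  "seed": null
}
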