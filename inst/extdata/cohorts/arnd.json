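{
  "group": "ARND",
  "n": 6,
  "p": {
    "A": [0.333040038910648, 0.393512450587009, 0.273447510502343, 0],
    "B": [0.699205822033421, 0.300794177966579, 0, 0],
    "C": [0.274670429679737, 0.227471019821897, 0.346211203950436, 0.151647346547931],
    "D": [0.356261488363503, 0.356261488363503, 0.287477023272994, 0]
  },
  "dependence": 0.487674540039837,
  "seed": null
}
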