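{
  "group": "ADHD",
  "n": 33,
  "p": {
    "A": [0.532435135402952, 0.467564864597048, 0, 0],
    "B": [0.540605943110142, 0.150007060818571, 0.309386996071286, 0],
    "C": [0.530112633379529, 0.0020073085913112, 0.467880058029159, 0],
    "D": [0.533713504659796, 0.0712668681451329, 0.395019627195071, 0]
  },
  "dependence": 0.463495507164165,
  "seed": null
}
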