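{
  "group": "FASD",
  "n": 37,
  "p": {
    "A": [0.575854184629984, 0.168210622201135, 0.127967596584441, 0.127967596584441],
    "B": [0.388712968344304, 0.385472785980944, 0.112907122837376, 0.112907122837376],
    "C": [0.2, 0.26306970147416, 0.13693029852584, 0.4],
    "D": [0.252349588203086, 0.179257008847834, 0.325442167558339, 0.242951235390741]
  },
  "dependence": 0.326670786072032,
  "seed": null
}
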