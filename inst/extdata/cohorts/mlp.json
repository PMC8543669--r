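{
  "group": "MLP",
  "n": 57,
  "p": {
    "A": [0.637786560761742, 0.2, 0.162213439238258, 0],
    "B": [0.811031102785772, 0.112542464728035, 0.0764264324861934, 0],
    "C": [0.769054835302972, 0.106079466958993, 0.124865697738035, 0],
    "D": [0.64457185984243, 0.18927523020104, 0.0543890774108453, 0.111763832545685]
  },
  "dependence": 0.25,
  "seed": null
}
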