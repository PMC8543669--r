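{
  "group": "SRS",
  "n": 16,
  "p": {
    "A": [0.726594531422739, 0.273405468577261, 0, 0],
    "B": [0.503772964542963, 0.272327940104609, 0.111949547676214, 0.111949547676214],
    "C": [0.665945546473779, 0.138640527106624, 0.195413926419598, 0],
    "D": [0.197576362309757, 0.261077797600755, 0.146193115469975, 0.395152724619513]
  },
  "dependence": 0.265968294236012,
  "seed": null
}
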