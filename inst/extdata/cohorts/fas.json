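{
  "group": "FAS",
  "n": 21,
  "p": {
    "A": [0.295505087109486, 0.251510551254266, 0.106339250672262, 0.346645110963986],
    "B": [0.6, 0.0783693582440416, 0.177952313112716, 0.143678328643243],
    "C": [0.145626190585104, 0.174832927692014, 0.222556529250711, 0.456984352472172],
    "D": [0.200953953442509, 0.137978254952885, 0.259159884719589, 0.401907906885017]
  },
  "dependence": 0.0169127823090772,
  "seed": null
}
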