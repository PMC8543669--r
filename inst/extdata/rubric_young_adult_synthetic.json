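{
  "name": "eyecode-young-adult-synthetic",
  "version": "1.0",
  "age_preset": "young_adult",
  "comment": "Young-adult preset: myopia cut-off raised to 2.0 D spherical equivalent to reflect the age dependence of refraction; other bands as in the child preset.",
  "eye_aggregation": { "acuity": "worse_eye", "refraction": "worse_eye" },
  "acuity_breaks": [0.8, 0.5, 0.3],
  "refraction": {
    "myopia_se_breaks": [2.0, 3.5, 5.0],
    "hypermetropia_se_breaks": [2.0, 4.0, 6.0],
    "astigmatism_breaks": [1.0, 2.0, 3.0],
    "anisometropia_breaks": [1.0, 2.0, 3.0]
  },
  "strabismus_scores": {
    "none": 1,
    "heterophoria": 2,
    "intermittent_tropia": 3,
    "manifest_tropia": 4
  },
  "stereo": {
    "seconds_breaks": [120, 480],
    "fail_score": 4,
    "untestable_score": 4,
    "max_seconds": 4000
  },
  "structural_count_breaks": [1, 2, 3]
}
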