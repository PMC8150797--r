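{
  "application_order": ["Korean", "Vietnamese"],
  "fallback_label": "neither",
  "origins": {
    "Korean": [
      {"variable": "P8",  "lower": null,  "upper": 4.945, "lower_inclusive": false, "upper_inclusive": false},
      {"variable": "P12", "lower": null,  "upper": 1.155, "lower_inclusive": false, "upper_inclusive": false},
      {"variable": "P14", "lower": null,  "upper": 1.555, "lower_inclusive": false, "upper_inclusive": false},
      {"variable": "P17", "lower": 0.620, "upper": 0.945, "lower_inclusive": true,  "upper_inclusive": true}
    ],
    "Vietnamese": [
      {"variable": "P8",  "lower": 3.445, "upper": null,  "lower_inclusive": false, "upper_inclusive": false},
      {"variable": "P12", "lower": 1.305, "upper": null,  "lower_inclusive": false, "upper_inclusive": false},
      {"variable": "P14", "lower": 0.985, "upper": 2.085, "lower_inclusive": true,  "upper_inclusive": true},
      {"variable": "P17", "lower": null,  "upper": 0.699, "lower_inclusive": false, "upper_inclusive": false}
    ]
  }
}
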