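{
  "format": "tpa-state-table/1",
  "units": {
    "energy": "hartree",
    "dipole": "au"
  },
  "energy_reference": "ground",
  "states": [
    {
      "index": 0,
      "label": "S0"
    },
    {
      "index": 1,
      "label": "S1"
    }
  ],
  "energies": [0, 0.0926082918826506],
  "dipoles": [
    [
      [0, 0, 0],
      [4.13101815, 0, 0]
    ],
    [
      [4.13101815, 0, 0],
      [1.73109332, 0, 0]
    ]
  ],
  "provenance": {
    "system": "egfp",
    "source": "built-in fixture"
  }
}
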