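{
  "stack_file": "bcg_sensor.json",
  "particle": {
    "volume_um3": 0.3887,
    "refractive_index": 1.35,
    "packing_fraction": 0.74,
    "fill_factor": 0.524
  },
  "spot_diameter_mm": 1,
  "mass_conversion_k": 600,
  "seed": 1,
  "peptides": [
    {
      "name": "6K-AH1",
      "molecular_weight": 1868.21,
      "anchor": "polyK",
      "immobilization_response_deg": 0.51528,
      "binding_response_deg": 0.058833333333333335
    },
    {
      "name": "6K-TRP2",
      "molecular_weight": 1944.4,
      "anchor": "polyK",
      "immobilization_response_deg": 0.31008,
      "binding_response_deg": 0.5026666666666667
    },
    {
      "name": "CPP-SIINFEKL",
      "molecular_weight": 3279.9,
      "anchor": "CPP",
      "immobilization_response_deg": 0.2508,
      "binding_response_deg": 0.2716666666666667
    }
  ]
}
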