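{
  "wavelength_nm": 670,
  "layers": [
    { "name": "prism", "n_real": 1.5151, "n_imag": 0, "thickness_nm": null },
    { "name": "Cr", "n_real": 3.0, "n_imag": 3.5, "thickness_nm": 2 },
    { "name": "Au", "n_real": 0.14, "n_imag": 3.515, "thickness_nm": 50 },
    { "name": "SiO2", "n_real": 1.456, "n_imag": 0, "thickness_nm": 15 },
    { "name": "ambient", "n_real": 1.335, "n_imag": 0, "thickness_nm": null }
  ]
}
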