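{
  "nuclide": "Lu-177",
  "version": "1.0",
  "half_life_days": 6.67,
  "electron_mev_per_decay": 0.1479,
  "photon_mev_per_decay": 0.0334,
  "notes": "Half-life matches the package's radiobiology defaults (decay constant 0.103/day). Mean electron energy per decay combines the beta spectrum with conversion and Auger electrons; mean photon energy combines the 113 and 208 keV gamma lines weighted by intensity. Values are the package's bundled constants (ICRP-107-scale), kept explicit and swappable here rather than hard-coded."
}
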