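{
  "biomass_fractions": [0.55, 0.2, 0.17, 0.08],
  "net_photosynthesis": 100,
  "lue": null,
  "maintenance_atp": 7.5,
  "vc_vo_default": 3,
  "seed": 1
}
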