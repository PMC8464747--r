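# Example site configuration: Allegheny Plateau pasture on a silt-loam
# holding 9 inches of plant-available water, cool-season sward.
site:
  latitude: 39.6
  asw_max_inches: 9
plant:
  preset: c3
  tsum_start: 280
et:
  pan_model: hargreaves
  et_pan_fraction: 0.80
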