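# Annual totals from a rotationally stocked cool-season pasture study on the
# Allegheny Plateau (West Virginia): observed cumulative forage growth
# (kg DM/ha) and the model's end-of-year cumulative environmental relative
# growth rate for a drought year (1999) and the preceding non-drought year.
year,cum_fg_obs_kg_ha,cum_rgr_env
1998,5736,174
1999,3323,92
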