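scenario,source,target,probability_pct,neighborhood_min,allowed_zones
settlement_expansion,4,1,50,1,EAST;CORRIDOR
settlement_expansion,6,1,90,1,EAST;CORRIDOR
settlement_expansion,3,1,50,1,EAST;CORRIDOR
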