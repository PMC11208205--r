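scenario,source,target,probability_pct,neighborhood_min,allowed_zones
rubber_expansion,4,2,85,1,WEST
rubber_expansion,6,2,90,1,WEST
rubber_expansion,3,2,60,1,WEST
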