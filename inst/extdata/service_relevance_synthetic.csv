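service_id,relevance
food,4.8
marketable,4.6
fuelwood,4.4
soil_quality,4.2
species_diversity,4.3
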