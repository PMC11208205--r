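service_id,name,indicator
food,Food provision,Share of products used as food for human consumption (percent)
marketable,Marketable products,Share of products sold for household income (percent)
fuelwood,Fuelwood provision,Share of products used as household fuelwood (percent)
soil_quality,Soil quality regulation,Litter production and decomposition rate (percent; expert Delphi survey)
species_diversity,Species diversity,Shannon-Wiener diversity of sampled species per class (rescaled by the cross-class maximum)
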