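class_id,name,description
1,Settlement,"Residential, industrial and infrastructural areas, roads and other built surfaces"
2,Rubber plantations,"Rubber plantations, including smallholder out-grower schemes"
3,Palm vegetation,"Smallholder and estate oil-palm plantations and coconut fields"
4,Cropland,"Annual and biannual food-crop farms (plantain, cassava, cocoyam, vegetables)"
5,Forest,"Closed-canopy forest reserve"
6,Shrubland,"Woody vegetation, bushes, open areas and fallow land"
7,Waterbody,"Rivers and other watercourses"
8,Wetlands,"Wetlands with mangroves"
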