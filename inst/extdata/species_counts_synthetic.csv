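class_id,species,count
1,ornamental_tree,30
2,hevea_brasiliensis,500
3,oil_palm,80
3,coconut,20
4,cassava,20
4,plantain,18
4,cocoyam,15
4,maize,14
4,yam,12
4,leafy_vegetables,10
4,legumes,8
4,pepper,7
5,forest_tree_01,8
5,forest_tree_02,10
5,forest_tree_03,12
5,forest_tree_04,8
5,forest_tree_05,10
5,forest_tree_06,12
5,forest_tree_07,8
5,forest_tree_08,10
5,forest_tree_09,12
5,forest_tree_10,8
5,forest_tree_11,10
5,forest_tree_12,12
5,forest_tree_13,8
5,forest_tree_14,10
5,forest_tree_15,12
5,forest_tree_16,8
5,forest_tree_17,10
5,forest_tree_18,12
5,forest_tree_19,8
5,forest_tree_20,10
5,forest_tree_21,12
5,forest_tree_22,8
5,forest_tree_23,10
5,forest_tree_24,12
5,forest_tree_25,8
5,forest_tree_26,10
5,forest_tree_27,12
6,acacia,40
6,chromolaena,25
6,baphia,15
6,grasses,12
6,ficus,8
7,tilapia,50
7,catfish,30
7,mudfish,20
8,red_mangrove,40
8,white_mangrove,25
8,mangrove_crab,15
8,oyster,10
8,periwinkle,6
8,heron,4
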