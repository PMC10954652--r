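class_id,resource,season,mean,sd,units
shrub_herb,nectar,fall,0.414,0.235,score
shrub_herb,nectar,spring,0.447,0.272,score
shrub_herb,milkweed,spring,0.233,0.170,score
cropland,nectar,fall,0.439,0.254,score
cropland,nectar,spring,0.418,0.293,score
cropland,milkweed,spring,0.263,0.212,score
wetland_herb,nectar,fall,0.201,0.119,score
wetland_herb,nectar,spring,0.237,0.134,score
wetland_herb,milkweed,spring,0.146,0.120,score
wetland_tree,nectar,fall,0.380,0.222,score
wetland_tree,nectar,spring,0.411,0.251,score
wetland_tree,milkweed,spring,0.267,0.204,score
bare,nectar,fall,0.332,0.215,score
bare,nectar,spring,0.402,0.205,score
bare,milkweed,spring,0.237,0.180,score
built_up,nectar,fall,0.410,0.253,score
built_up,nectar,spring,0.418,0.274,score
built_up,milkweed,spring,0.251,0.199,score
tree_cover,nectar,fall,0.404,0.249,score
tree_cover,nectar,spring,0.474,0.272,score
tree_cover,milkweed,spring,0.287,0.226,score
water,nectar,fall,0,0,score
water,nectar,spring,0,0,score
water,milkweed,spring,0,0,score
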