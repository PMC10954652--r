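class_id,resource,season,mean,sd,units
dev_open,nectar,fall,0.460,0.254,score
dev_open,nectar,spring,0.461,0.293,score
dev_open,milkweed,spring,28.5,58.0,plants_per_ha
dev_low,nectar,fall,0.477,0.242,score
dev_low,nectar,spring,0.533,0.185,score
dev_low,milkweed,spring,9.6,23.0,plants_per_ha
dev_med,nectar,fall,0.393,0.240,score
dev_med,nectar,spring,0.402,0.235,score
dev_med,milkweed,spring,6.2,17.9,plants_per_ha
dev_high,nectar,fall,0.263,0.178,score
dev_high,nectar,spring,0.317,0.210,score
dev_high,milkweed,spring,3.3,8.5,plants_per_ha
barren,nectar,fall,0.22,0.124,score
barren,nectar,spring,0.25,0.133,score
barren,milkweed,spring,0,0,plants_per_ha
deciduous,nectar,fall,0.399,0.328,score
deciduous,nectar,spring,0.714,0.281,score
deciduous,milkweed,spring,37.4,185.1,plants_per_ha
evergreen,nectar,fall,0.366,0.254,score
evergreen,nectar,spring,0.438,0.299,score
evergreen,milkweed,spring,6.2,18.0,plants_per_ha
mixed,nectar,fall,0.378,0.324,score
mixed,nectar,spring,0.594,0.325,score
mixed,milkweed,spring,50.8,142.7,plants_per_ha
shrubland,nectar,fall,0.456,0.325,score
shrubland,nectar,spring,0.685,0.234,score
shrubland,milkweed,spring,8.9,46.2,plants_per_ha
grass,nectar,fall,0.491,0.383,score
grass,nectar,spring,0.574,0.334,score
grass,milkweed,spring,66.8,195.5,plants_per_ha
pasture,nectar,fall,0.366,0.223,score
pasture,nectar,spring,0.298,0.252,score
pasture,milkweed,spring,21.6,118.3,plants_per_ha
cropland,nectar,fall,0.329,0.286,score
cropland,nectar,spring,0.308,0.286,score
cropland,milkweed,spring,0,0,plants_per_ha
wetland_woody,nectar,fall,0.434,0.299,score
wetland_woody,nectar,spring,0.587,0.193,score
wetland_woody,milkweed,spring,0,0,plants_per_ha
wetland_herb,nectar,fall,0.458,0.340,score
wetland_herb,nectar,spring,0.463,0.201,score
wetland_herb,milkweed,spring,0,0,plants_per_ha
water,nectar,fall,0,0,score
water,nectar,spring,0,0,score
water,milkweed,spring,0,0,plants_per_ha
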