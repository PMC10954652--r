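class_id,label,start_area_km2,end_area_km2,loss_km2,gain_km2
barren,Barren,2251,1922,690,361
cropland,Cultivated crops,43589,47101,1290,4802
dev_high,Developed high intensity,2306,3396,0.4,1090
dev_low,Developed low intensity,9285,10421,495,1631
dev_med,Developed medium intensity,5378,8127,35,2784
dev_open,Developed open space,13553,13652,1255,1355
deciduous,Deciduous forest,18983,18105,2059,1181
evergreen,Evergreen forest,37933,38246,4847,5160
mixed,Mixed forest,14837,14401,1733,1297
grass,Herbaceous grassland,72387,69922,8196,5731
pasture,Pasture/hay,72955,67612,5875,532
shrubland,Shrub,193272,192920,8012,7659
water,Open water,16003,16969,394,1359
wetland_herb,Herbaceous wetlands,7066,6995,1288,1217
wetland_woody,Woody wetlands,18875,18883,92,101
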