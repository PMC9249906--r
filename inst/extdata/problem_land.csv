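code,typology,severity
1,too_cold,severe
2,too_dry,severe
3,steep_slope_gt30pct,severe
4,shallow,severe
5,poorly_drained,severe
6,saline_sodic,severe
7,acid_sulphate,severe
8,peat_organic_soil,severe
9,alluvial_soil_in_desert,severe
10,coarse_texture,moderate
11,vertisol,moderate
12,infertile_nutrient_poor,moderate
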