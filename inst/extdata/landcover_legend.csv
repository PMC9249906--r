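code,role,label
10,cropland,Cropland rainfed
11,cropland,Cropland rainfed herbaceous cover
12,cropland,Cropland rainfed tree or shrub cover
20,cropland,Cropland irrigated or post-flooding
30,mosaic_cropland,Mosaic cropland (>50%) / natural vegetation
40,mosaic_cropland,Mosaic natural vegetation (>50%) / cropland
50,other,Tree cover broadleaved evergreen
60,other,Tree cover broadleaved deciduous
70,other,Tree cover needleleaved evergreen
80,other,Tree cover needleleaved deciduous
90,other,Tree cover mixed leaf type
100,other,Mosaic tree and shrub (>50%) / herbaceous cover
110,herbaceous_mosaic,Mosaic herbaceous cover (>50%) / tree and shrub
120,shrubland,Shrubland
121,shrubland,Evergreen shrubland
122,shrubland,Deciduous shrubland
130,grassland,Grassland
140,other,Lichens and mosses
150,sparse,Sparse vegetation (tree shrub herbaceous <15%)
151,sparse,Sparse tree (<15%)
152,sparse,Sparse shrub (<15%)
153,sparse,Sparse herbaceous cover (<15%)
160,other,Tree cover flooded fresh or brackish water
170,other,Tree cover flooded saline water
180,other,Shrub or herbaceous cover flooded
190,other,Urban areas
200,bare,Bare areas
201,bare,Consolidated bare areas
202,bare,Unconsolidated bare areas
210,other,Water bodies
220,other,Permanent snow and ice
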