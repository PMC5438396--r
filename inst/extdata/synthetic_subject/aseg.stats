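# Table of structural measures (synthetic)
# Measure EstimatedTotalIntraCranialVol, EstimatedTotalIntraCranialVol, EstimatedTotalIntraCranialVol, 1470986.247601, mm^3
# Measure lhCerebralWhiteMatter, lhCerebralWhiteMatter, lhCerebralWhiteMatter, 244622.211478, mm^3
# Measure rhCerebralWhiteMatter, rhCerebralWhiteMatter, rhCerebralWhiteMatter, 231599.932605, mm^3
# Measure TotalGray, TotalGray, TotalGray, 579544.769701, mm^3
# ColHeaders Index SegId NVoxels Volume_mm3 StructName
   1    11     8648    8647.8563 Left-Lateral-Ventricle
   2    12      401     400.5023 Left-Inf-Lat-Vent
   3    13     7218    7218.4555 Left-Thalamus-Proper
   4    14     3875    3875.0752 Left-Caudate
   5    15     5973    5973.4430 Left-Putamen
   6    16     2030    2030.2877 Left-Pallidum
   7    17     3358    3357.5251 Left-Hippocampus
   8    18     1556    1556.3680 Left-Amygdala
   9    19      651     651.4564 Left-Accumbens-area
  10    20     3349    3348.5307 Left-VentralDC
  11    21     1498    1498.4965 Left-choroid-plexus
  12    22     9864    9863.6228 Right-Lateral-Ventricle
  13    23      362     362.3910 Right-Inf-Lat-Vent
  14    24     7012    7011.6947 Right-Thalamus-Proper
  15    25     3926    3925.5166 Right-Caudate
  16    26     4628    4628.0284 Right-Putamen
  17    27     1655    1655.0374 Right-Pallidum
  18    28     3968    3968.2435 Right-Hippocampus
  19    29     1648    1647.7970 Right-Amygdala
  20    30      539     538.6864 Right-Accumbens-area
  21    31     3382    3381.7383 Right-VentralDC
  22    32     1513    1513.1305 Right-choroid-plexus
  23    33      989     989.4558 3rd-Ventricle
  24    34     1826    1825.6960 4th-Ventricle
  25    35    21078   21078.1106 Brain-Stem
  26    36     1300    1300.0551 CSF
  27    37     1062    1062.0241 CC_Posterior
  28    38      445     445.3024 CC_Mid_Posterior
  29    39      475     475.3571 CC_Central
  30    40      502     501.7088 CC_Mid_Anterior
  31    41      911     911.3372 CC_Anterior
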