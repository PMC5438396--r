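# Table of structural measures (synthetic)
# Measure EstimatedTotalIntraCranialVol, EstimatedTotalIntraCranialVol, EstimatedTotalIntraCranialVol, 1470986.247601, mm^3
# ColHeaders StructName NumVert SurfArea GrayVol ThickAvg ThickStd
bankssts                       1700     1367.7     3412.9   2.4953   0.3474
caudalanteriorcingulate        1200      908.5     2338.4   2.5738   0.6304
caudalmiddlefrontal            3800     2353.9     5709.4   2.4256   0.6897
cuneus                         2500     1426.6     3639.5   2.5511   0.5817
entorhinal                      700      873.1     2078.9   2.3812   0.7151
frontalpole                     400      528.9     1311.6   2.4797   0.5472
fusiform                       5000     4113.7    10239.1   2.4890   0.6232
inferiorparietal               8200     4698.9    12910.8   2.7476   0.5378
inferiortemporal               5600     4513.7    10679.8   2.3661   0.6135
insula                         3500     3281.6     8082.9   2.4631   0.6381
isthmuscingulate               1600      874.2     2647.8   3.0288   0.6730
lateraloccipital               8300     4999.5    13204.4   2.6412   0.6031
lateralorbitofrontal           4400     2708.7     7240.4   2.6730   0.6368
lingual                        5100     2921.0     7501.1   2.5680   0.5821
medialorbitofrontal            3100     2237.8     5416.3   2.4204   0.7504
middletemporal                 5400     5004.4    12648.5   2.5274   0.8417
paracentral                    2500     1519.6     4272.7   2.8118   0.6026
parahippocampal                1200      860.4     2324.3   2.7014   0.5828
parsopercularis                2800     1869.3     4655.1   2.4903   0.5363
parsorbitalis                  1100     1032.9     2941.2   2.8475   0.5861
parstriangularis               2300     1568.3     4252.8   2.7118   0.4212
pericalcarine                  2400      890.5     2341.3   2.6294   0.7470
postcentral                    7000     4245.8    11202.9   2.6386   0.7121
posteriorcingulate             2000     1560.9     3902.6   2.5002   0.7543
precentral                     8400     6449.5    15458.1   2.3968   0.6133
precuneus                      6300     3669.0     9466.2   2.5801   0.5697
rostralanteriorcingulate       1300      937.9     2702.1   2.8811   0.7003
rostralmiddlefrontal           7600     5527.4    14534.5   2.6295   0.6636
superiorfrontal               11200     8617.4    23581.4   2.7365   0.6466
superiorparietal               8600     5503.9    13738.2   2.4961   0.5455
superiortemporal               6100     4349.9    12783.2   2.9387   0.6117
supramarginal                  6500     4264.6    11156.9   2.6162   0.6349
temporalpole                    800      621.3     2552.4   4.1085   0.6352
transversetemporal              800      485.7     1254.5   2.5827   0.7054
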