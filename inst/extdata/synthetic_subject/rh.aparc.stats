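# Table of structural measures (synthetic)
# Measure EstimatedTotalIntraCranialVol, EstimatedTotalIntraCranialVol, EstimatedTotalIntraCranialVol, 1470986.247601, mm^3
# ColHeaders StructName NumVert SurfArea GrayVol ThickAvg ThickStd
bankssts                       1700     1146.5     3081.3   2.6876   0.5571
caudalanteriorcingulate        1200      823.5     2139.2   2.5977   0.7224
caudalmiddlefrontal            3800     3432.3     7700.6   2.2436   0.6762
cuneus                         2500     1484.1     4047.5   2.7273   0.6313
entorhinal                      700      892.4     2446.4   2.7413   0.7956
frontalpole                     400      398.7     1027.0   2.5757   0.6511
fusiform                       5000     4277.1    10635.0   2.4865   0.7081
inferiorparietal               8200     7847.4    16703.0   2.1285   0.5950
inferiortemporal               5600     5534.9    12489.9   2.2566   0.7067
insula                         3500     2744.8     7032.4   2.5621   0.6249
isthmuscingulate               1600     1248.8     3003.8   2.4054   0.6706
lateraloccipital               8300     4854.4    13057.9   2.6899   0.6484
lateralorbitofrontal           4400     3415.5     8746.7   2.5609   0.7375
lingual                        5100     2544.8     6585.8   2.5880   0.6850
medialorbitofrontal            3100     2939.5     7436.2   2.5298   0.5673
middletemporal                 5400     5197.2    12658.0   2.4356   0.6425
paracentral                    2500     1354.8     3703.9   2.7338   0.5818
parahippocampal                1200      755.2     2064.7   2.7342   0.7327
parsopercularis                2800     1760.4     4497.0   2.5545   0.5993
parsorbitalis                  1100      979.8     2548.8   2.6013   0.5956
parstriangularis               2300     1614.1     4381.0   2.7142   0.6324
pericalcarine                  2400      932.2     2231.4   2.3938   0.6055
postcentral                    7000     4144.7    10723.1   2.5872   0.5627
posteriorcingulate             2000     1623.1     3898.4   2.4018   0.7872
precentral                     8400     5373.8    14264.4   2.6544   0.7122
precuneus                      6300     4544.2    11277.2   2.4817   0.7607
rostralanteriorcingulate       1300      967.2     2582.2   2.6698   0.5572
rostralmiddlefrontal           7600     4934.8    12113.0   2.4546   0.5843
superiorfrontal               11200     8267.2    21003.8   2.5406   0.5766
superiorparietal               8600     5302.7    13190.4   2.4875   0.6873
superiortemporal               6100     4578.6    12738.9   2.7823   0.6297
supramarginal                  6500     5642.5    14247.3   2.5250   0.5662
temporalpole                    800      707.6     2356.6   3.3302   0.6534
transversetemporal              800      432.3     1062.4   2.4573   0.6025
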