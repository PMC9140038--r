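frame,unregistered,registered_rgb,registered_red,registered_green,registered_blue,registered_grayscale
2,0.908,0.924,0.907,0.893,0.890,0.918
3,0.878,0.913,0.891,0.881,0.875,0.909
4,0.852,0.923,0.873,0.878,0.867,0.884
5,0.840,0.911,0.889,0.877,0.860,0.880
6,0.802,0.910,0.882,0.872,0.857,0.872
7,0.803,0.901,0.877,0.870,0.859,0.868
8,0.801,0.899,0.872,0.861,0.855,0.862
9,0.767,0.893,0.870,0.855,0.851,0.857
10,0.782,0.889,0.868,0.852,0.844,0.854
11,0.773,0.878,0.862,0.851,0.850,0.858
12,0.770,0.870,0.860,0.847,0.838,0.856
13,0.748,0.883,0.860,0.845,0.840,0.851
14,0.733,0.866,0.855,0.840,0.833,0.850
15,0.740,0.869,0.851,0.838,0.830,0.847
16,0.739,0.854,0.850,0.833,0.834,0.847
17,0.741,0.878,0.850,0.835,0.831,0.849
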