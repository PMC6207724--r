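residue_id,atom_group,delta_h_ppm,delta_n_ppm
1,backbone-NH,8.44548756734675,125.320261907723
2,backbone-NH,8.07933889258829,116.474949464496
3,backbone-NH,8.00609451024002,110.231976776396
4,backbone-NH,8.66171237431962,105.065047954461
5,backbone-NH,8.68173093454911,108.110317664127
6,backbone-NH,9.40172018054955,111.65077373566
7,backbone-NH,9.30012482140424,121.759705918331
8,backbone-NH,8.66833621421322,104.63445405887
9,backbone-NH,9.4261949285787,110.297656479798
10,backbone-NH,7.95077225366003,130.015273441158
11,backbone-NH,8.15992636375275,127.603112217923
12,backbone-NH,8.95523543777133,122.183099683856
13,backbone-NH,8.55686823103408,115.396099288808
14,backbone-NH,7.90552658988671,118.068654921148
15,backbone-NH,7.72026901620519,123.82049138136
16,backbone-NH,8.23745407699922,119.981068023892
17,backbone-NH,7.47146767437077,122.091884954462
18,backbone-NH,8.51380654501395,110.344494109005
19,backbone-NH,8.00424373816463,109.763853328561
20,backbone-NH,8.82551312025052,113.834577157735
21,backbone-NH,7.93458369670438,128.035824866432
22,backbone-NH,8.20595865894413,128.780970161978
23,backbone-NH,8.26440921291031,126.50623957843
24,backbone-NH,7.23090948116855,125.905500154217
25,backbone-NH,8.62357201846944,118.616070397898
26,backbone-NH,7.85135219389946,104.012768682111
27,backbone-NH,8.33293918373939,120.413692499032
28,backbone-NH,8.7876817988067,123.086698689175
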