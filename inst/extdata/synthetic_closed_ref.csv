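residue_id,atom_group,delta_h_ppm,delta_n_ppm
1,backbone-NH,8.39573227703046,125.454249712912
2,backbone-NH,8.10652501474025,116.157620243834
3,backbone-NH,8.01424942412304,110.165949483172
4,backbone-NH,8.67618285161825,104.815573377319
5,backbone-NH,8.66328830957291,108.202075188335
6,backbone-NH,9.39368137465202,111.518717090218
7,backbone-NH,9.3307970341198,121.73722617485
8,backbone-NH,8.66775380750227,104.601960274802
9,backbone-NH,9.45495685635585,110.292821005056
10,backbone-NH,7.95474782053582,130.18031529122
11,backbone-NH,8.17242321823089,127.565459429824
12,backbone-NH,8.92841847605561,122.066596376092
13,backbone-NH,8.51553509228606,115.661547885641
14,backbone-NH,7.89434224280352,118.123520695953
15,backbone-NH,7.73934899938476,123.844372377077
16,backbone-NH,8.29074217029344,119.908694099317
17,backbone-NH,7.4158358856618,122.231727400881
18,backbone-NH,8.52338416711284,110.311371731972
19,backbone-NH,8.018762135506,109.710761710909
20,backbone-NH,8.81042870147445,113.690123264741
21,backbone-NH,7.98062403441318,127.989704838671
22,backbone-NH,8.19918018252062,128.745623939657
23,backbone-NH,8.2366849759756,126.86502340414
24,backbone-NH,7.20299346940546,126.20703995846
25,backbone-NH,8.61390654566752,118.637641945553
26,backbone-NH,7.85461400255076,103.888923829386
27,backbone-NH,8.34597765115331,120.436335907842
28,backbone-NH,8.7876708233385,122.75541649564
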