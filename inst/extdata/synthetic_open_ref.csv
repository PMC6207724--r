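residue_id,atom_group,delta_h_ppm,delta_n_ppm
1,backbone-NH,8.85455366037786,124.395584065933
2,backbone-NH,7.84252866078168,119.091171039036
3,backbone-NH,8.02217592764646,110.842584965285
4,backbone-NH,8.5288258693181,107.249512908747
5,backbone-NH,8.85121454903856,107.140301623149
6,backbone-NH,9.46563439583406,112.63045923668
7,backbone-NH,9.01908853510395,121.685662866803
8,backbone-NH,8.63297684816644,105.00597241451
9,backbone-NH,9.1993794371374,110.214248923585
10,backbone-NH,7.87894787080586,128.325853183633
11,backbone-NH,8.04257322940975,128.141118715284
12,backbone-NH,9.15631697047502,123.352357525146
13,backbone-NH,8.88640964077786,113.326799585484
14,backbone-NH,7.98108947928995,117.876583245816
15,backbone-NH,7.58597759203985,123.599366158014
16,backbone-NH,7.78095818823203,120.47898100107
17,backbone-NH,7.93277083011344,120.656133613084
18,backbone-NH,8.45879712840542,110.42894245591
19,backbone-NH,7.89482068456709,110.414182774257
20,backbone-NH,8.93871167534962,114.723625716288
21,backbone-NH,7.51576947746798,128.561392299598
22,backbone-NH,8.25097992923111,129.065200344194
23,backbone-NH,8.52881541661918,123.496381980367
24,backbone-NH,7.50314110843465,123.331147643039
25,backbone-NH,8.66320800501853,118.394032249926
26,backbone-NH,7.81581041635945,105.056824152125
27,backbone-NH,8.21805661171675,120.223436313681
28,backbone-NH,8.79126375680789,125.920038985787
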