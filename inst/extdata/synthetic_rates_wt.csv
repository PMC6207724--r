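ligand_uM,k_fast_s,k_slow_s
10,5.18799,2.47762
15,7.19083,2.67478
20,9.31623,2.74938
30,13.65546,2.81015
40,18.02948,2.83612
60,26.80603,2.85958
80,35.59517,2.87044
100,44.3889,2.87671
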