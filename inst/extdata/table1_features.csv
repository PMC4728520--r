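feature_id,rt_min,mz,intensity,spectrum_id,compound
M2_01,4.56,188.1070,100,M2_01,Pseudane-III
M2_02,5.32,202.1227,100,M2_02,Pseudane-IV
M2_03,5.99,216.1382,100,M2_03,2-isopentylquinolin-4-one
M2_04,6.09,216.1382,100,M2_04,Pseudane-V
M2_05,6.71,230.1539,100,M2_05,"2-(2,3-dimethylbutyl)quinolin-4-one"
M2_06,6.83,230.1539,100,M2_06,Pseudane-VI
M2_07,7.55,244.1695,100,M2_07,Pseudane-VII
M2_08,8.29,258.1851,100,M2_08,Pseudane-VIII
M2_09,9.00,272.2007,100,M2_09,Pseudane-IX
M2_10,9.67,286.2164,100,M2_10,Pseudane-X
M2_11,10.33,300.2322,100,M2_11,Pseudane-XI
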