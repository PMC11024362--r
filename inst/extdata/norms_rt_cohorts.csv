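metric,sex,age_bin,mean,band_1,band_1p5,band_2
rt_hit,male,21-31,879,1042,1124,1205
rt_hit,male,31-40,876,1039,1121,1202
rt_hit,male,41-51,884,1047,1129,1210
rt_hit,male,51-60,902,1066,1148,1229
rt_hit,male,61-70,932,1095,1177,1258
rt_hit,male,71-81,972,1135,1217,1298
rt_hit,male,81-90,1023,1186,1268,1349
rt_hit,female,21-31,864,1020,1098,1176
rt_hit,female,31-40,863,1019,1097,1175
rt_hit,female,41-51,874,1030,1108,1186
rt_hit,female,51-60,897,1053,1131,1209
rt_hit,female,61-70,933,1089,1167,1245
rt_hit,female,71-81,982,1138,1216,1294
rt_hit,female,81-90,1043,1199,1277,1355
rt_fa,male,21-31,1027,1444,1653,1861
rt_fa,male,31-40,1008,1425,1634,1842
rt_fa,male,41-51,1008,1426,1635,1843
rt_fa,male,51-60,1028,1445,1654,1862
rt_fa,male,61-70,1067,1484,1693,1901
rt_fa,male,71-81,1125,1542,1751,1959
rt_fa,male,81-90,1202,1619,1828,2036
rt_fa,female,21-31,984,1396,1602,1809
rt_fa,female,31-40,965,1377,1583,1789
rt_fa,female,41-51,968,1380,1586,1792
rt_fa,female,51-60,992,1404,1610,1816
rt_fa,female,61-70,1038,1450,1656,1862
rt_fa,female,71-81,1106,1518,1724,1930
rt_fa,female,81-90,1195,1607,1813,2020
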