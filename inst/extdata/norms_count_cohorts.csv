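metric,sex,age_bin,mean,band_1,band_1p5,band_2
hits,male,21-31,23.5,21.4,20.4,19.3
hits,male,31-40,23.5,21.4,20.4,19.3
hits,male,41-51,23.4,21.3,20.3,19.2
hits,male,51-60,23.3,21.2,20.2,19.1
hits,male,61-70,23.2,21.1,20.1,18.9
hits,male,71-81,23.0,20.9,19.9,18.7
hits,male,81-90,22.8,20.6,19.5,18.5
hits,female,21-31,23.4,21.3,20.3,19.3
hits,female,31-40,23.4,21.4,20.4,19.4
hits,female,41-51,23.4,21.3,20.3,19.3
hits,female,51-60,23.2,21.2,20.2,19.1
hits,female,61-70,22.9,20.9,19.9,18.8
hits,female,71-81,22.5,20.4,19.4,18.4
hits,female,81-90,21.9,19.9,18.9,17.9
crs,male,21-31,24.1,23.2,22.8,22.3
crs,male,31-40,24.1,23.2,22.8,22.3
crs,male,41-51,24.0,23.1,22.7,22.2
crs,male,51-60,23.9,23.0,22.6,22.1
crs,male,61-70,23.8,22.9,22.5,21.9
crs,male,71-81,23.6,22.7,22.3,21.8
crs,male,81-90,23.4,22.5,22.1,21.6
crs,female,21-31,24.0,23.0,22.5,22.0
crs,female,31-40,24.0,23.0,22.5,22.0
crs,female,41-51,23.9,22.9,22.4,21.9
crs,female,51-60,23.8,22.8,22.3,21.8
crs,female,61-70,23.6,22.6,22.1,21.6
crs,female,71-81,23.4,22.4,21.9,21.4
crs,female,81-90,23.2,22.2,21.7,21.2
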