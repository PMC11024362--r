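metric,score,percentile,z
tc,50,99.90,3.09
tc,49,86.65,1.11
tc,48,65.41,0.40
tc,47,44.87,-0.13
tc,46,28.94,-0.56
tc,45,17.63,-0.93
tc,44,10.90,-1.23
tc,43,6.93,-1.48
tc,42,4.62,-1.68
tc,41,3.02,-1.88
tc,40,2.06,-2.04
tc,39,1.36,-2.21
tc,38,0.95,-2.35
tc,37,0.64,-2.49
tc,36,0.46,-2.60
tc,35,0.36,-2.69
tc,34,0.24,-2.82
tc,33,0.10,-3.08
hits,25,99.90,3.09
hits,24,67.91,0.47
hits,23,40.51,-0.24
hits,22,23.21,-0.73
hits,21,13.82,-1.09
hits,20,8.18,-1.39
hits,19,5.14,-1.63
hits,18,3.41,-1.82
hits,17,2.27,-2.00
hits,16,1.54,-2.16
hits,15,1.09,-2.29
hits,14,0.72,-2.45
hits,13,0.57,-2.53
hits,12,0.38,-2.67
hits,11,0.28,-2.77
hits,10,0.19,-2.90
hits,9,0.10,-3.08
crs,25,99.90,3.09
crs,24,62.83,0.33
crs,23,27.71,-0.59
crs,22,9.96,-1.28
crs,21,3.48,-1.81
crs,20,1.17,-2.27
crs,19,0.28,-2.77
crs,18,0.13,-3.01
crs,17,0.08,-3.17
crs,16,0.04,-3.33
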