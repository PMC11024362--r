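rt_ms,percentile,z
560,100.0,3.9
580,100.0,3.4
600,99.9,3.0
620,99.6,2.6
640,99.1,2.4
660,98.2,2.1
680,96.7,1.8
700,94.5,1.6
720,91.1,1.3
740,87.4,1.1
760,82.6,0.9
780,77.1,0.7
800,70.9,0.6
820,64.7,0.4
840,58.6,0.2
860,52.3,0.1
880,46.3,-0.1
900,40.7,-0.2
920,35.6,-0.4
940,31.0,-0.5
960,26.9,-0.6
980,23.4,-0.7
1000,20.3,-0.8
1020,17.3,-0.9
1040,14.8,-1.0
1060,12.7,-1.1
1080,11.0,-1.2
1100,9.4,-1.3
1120,8.1,-1.4
1140,7.1,-1.5
1160,6.1,-1.5
1180,5.2,-1.6
1200,4.5,-1.7
1220,4.0,-1.8
1240,3.4,-1.8
1260,2.9,-1.9
1280,2.4,-2.0
1300,2.1,-2.0
1320,1.8,-2.1
1340,1.6,-2.1
1360,1.4,-2.2
1380,1.2,-2.3
1400,1.0,-2.3
1420,0.9,-2.4
1440,0.8,-2.4
1460,0.7,-2.5
1480,0.6,-2.5
1500,0.6,-2.5
1520,0.5,-2.6
1540,0.5,-2.6
1560,0.4,-2.7
1580,0.3,-2.7
1600,0.3,-2.8
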