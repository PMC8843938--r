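element,energy_kev,mu_rho_cm2_g
H,10,0.3854
H,15,0.3764
H,20,0.3695
H,30,0.3570
H,40,0.3458
H,50,0.3355
H,60,0.3260
H,80,0.3091
H,100,0.2944
H,150,0.2651
C,10,2.373
C,15,0.8071
C,20,0.4420
C,30,0.2562
C,40,0.2076
C,50,0.1871
C,60,0.1753
C,80,0.1610
C,100,0.1514
C,150,0.1347
N,10,3.879
N,15,1.236
N,20,0.6178
N,30,0.3066
N,40,0.2288
N,50,0.1980
N,60,0.1817
N,80,0.1639
N,100,0.1529
N,150,0.1353
O,10,5.952
O,15,1.836
O,20,0.8651
O,30,0.3779
O,40,0.2585
O,50,0.2132
O,60,0.1907
O,80,0.1678
O,100,0.1551
O,150,0.1361
Al,10,26.23
Al,15,7.955
Al,20,3.441
Al,30,1.128
Al,40,0.5685
Al,50,0.3681
Al,60,0.2778
Al,80,0.2018
Al,100,0.1704
Al,150,0.1378
Cl,10,18.42
Cl,15,6.065
Cl,20,2.661
Cl,30,0.8852
Cl,40,0.4664
Cl,50,0.3299
Cl,60,0.2676
Cl,80,0.2103
Cl,100,0.1854
Cl,150,0.1539
I,10,162.0
I,15,54.03
I,20,25.43
I,30,8.561
I,33.16,6.553
I,33.18,36.00
I,40,22.10
I,50,12.32
I,60,7.579
I,80,3.510
I,100,1.942
I,150,0.6978
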