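geometry,mdf,ndf,mdf_L,mdf_R,ndf_L,ndf_R
mb,85.30,23.10,23.50,76.50,40.20,59.80
mm,62.70,40.50,42.50,57.50,41.10,58.90
ms,52.40,30.80,14.20,85.80,33.90,66.10
bb,48.00,44.90,24.40,75.60,49.80,50.20
bm,81.50,40.90,81.30,18.70,50.20,49.80
bs,57.00,46.20,62.20,37.80,59.20,40.80
sb,57.90,39.30,37.40,62.20,29.10,70.90
sm,62.00,26.10,34.60,65.40,46.00,54.00
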