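material,tissue_class,energy_kev,mu_per_mm
air,air,40,3.2196e-05
air,air,50,2.7228e-05
air,air,60,2.4708e-05
air,air,70,2.3148e-05
air,air,80,2.2044e-05
air,air,90,2.1192e-05
air,air,100,2.0484e-05
air,air,110,1.9848e-05
air,air,120,1.9332e-05
air,air,500,1.1628e-05
air,air,1000,8.484e-06
water,water,40,0.02683
water,water,50,0.02269
water,water,60,0.02059
water,water,70,0.01929
water,water,80,0.01837
water,water,90,0.01766
water,water,100,0.01707
water,water,110,0.01654
water,water,120,0.01611
water,water,500,0.00969
water,water,1000,0.00707
soft_tissue,soft,40,0.028172
soft_tissue,soft,50,0.023824
soft_tissue,soft,60,0.02162
soft_tissue,soft,70,0.020254
soft_tissue,soft,80,0.019288
soft_tissue,soft,90,0.018543
soft_tissue,soft,100,0.017924
soft_tissue,soft,110,0.017367
soft_tissue,soft,120,0.016916
soft_tissue,soft,500,0.010175
soft_tissue,soft,1000,0.0074235
lung,low_density,40,0.008049
lung,low_density,50,0.006807
lung,low_density,60,0.006177
lung,low_density,70,0.005787
lung,low_density,80,0.005511
lung,low_density,90,0.005298
lung,low_density,100,0.005121
lung,low_density,110,0.004962
lung,low_density,120,0.004833
lung,low_density,500,0.002907
lung,low_density,1000,0.002121
bone,bone,40,0.12778
bone,bone,50,0.081446
bone,bone,60,0.060442
bone,bone,70,0.050477
bone,bone,80,0.042797
bone,bone,90,0.039206
bone,bone,100,0.035616
bone,bone,110,0.034368
bone,bone,120,0.033139
bone,bone,500,0.017357
bone,bone,1000,0.012614
titanium,metal,40,0.87507
titanium,metal,50,0.54658
titanium,metal,60,0.37977
titanium,metal,70,0.29339
titanium,metal,80,0.22404
titanium,metal,90,0.19331
titanium,metal,100,0.16487
titanium,metal,110,0.15118
titanium,metal,120,0.13743
titanium,metal,500,0.036909
titanium,metal,1000,0.026486
amalgam,metal,40,4.8
amalgam,metal,50,2.7
amalgam,metal,60,1.72
amalgam,metal,70,1.25
amalgam,metal,80,0.9
amalgam,metal,90,0.7
amalgam,metal,100,0.56
amalgam,metal,110,0.47
amalgam,metal,120,0.4
amalgam,metal,500,0.0846
amalgam,metal,1000,0.0585
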