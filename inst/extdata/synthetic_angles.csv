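group,theta_deg
myoblast_fn,6.948
myoblast_fn,-5.89
myoblast_fn,12.653
myoblast_fn,-20.827
myoblast_fn,11.77
myoblast_fn,-2.191
myoblast_fn,-0.667
myoblast_fn,-11.298
myoblast_fn,5.382
myoblast_fn,3.721
myoblast_fn,-4.333
myoblast_fn,-25.638
myoblast_fn,12.906
myoblast_fn,-25.827
myoblast_fn,-9.899
myoblast_fn,-6.191
myoblast_fn,-11.448
myoblast_fn,-12.363
myoblast_fn,-9.486
myoblast_fn,7.25
myoblast_fn,-0.874
myoblast_fn,-7.889
myoblast_fn,-8.022
myoblast_fn,-4.195
myoblast_fn,-19.531
myoblast_fn,-1.52
myoblast_fn,-15.044
myoblast_fn,-7.256
myoblast_fn,1.693
myoblast_fn,13.138
myoblast_fn,8.019
myoblast_fn,2.917
myoblast_fn,-18.72
myoblast_fn,-15.507
myoblast_fn,1.185
myoblast_fn,-23.107
myoblast_fn,-10.044
myoblast_fn,-30.558
myoblast_fn,-13.764
myoblast_fn,-9.583
myoblast_fn,-21.402
myoblast_fn,0.114
myoblast_fn,11.925
myoblast_fn,-32.693
myoblast_fn,-17.632
myoblast_fn,-21.47
myoblast_fn,-8.2
myoblast_fn,-6.414
myoblast_fn,9.495
myoblast_fn,-17.039
myoblast_fn,0.732
myoblast_fn,-20.523
myoblast_fn,-9.67
myoblast_fn,-20.869
myoblast_fn,-10.186
myoblast_fn,-25.059
myoblast_fn,15.876
myoblast_fn,15.764
myoblast_fn,7.96
myoblast_fn,-26.275
myoblast_fn,-18.952
myoblast_fn,-11.245
myoblast_fn,-8.885
myoblast_fn,15.733
myoblast_fn,3.942
myoblast_fn,-9.015
myoblast_fn,4.439
myoblast_fn,11.325
myoblast_fn,-5.128
myoblast_fn,-6.024
myoblast_fn,-18.659
myoblast_fn,10.941
myoblast_fn,0.826
myoblast_fn,-3.61
myoblast_fn,-10.789
myoblast_fn,-20.613
myoblast_fn,-16.243
myoblast_fn,-16.338
myoblast_fn,-5.127
myoblast_fn,-21.691
osteoblast_fn,22.866
osteoblast_fn,23.746
osteoblast_fn,-20.768
osteoblast_fn,15.503
osteoblast_fn,10.347
osteoblast_fn,13.922
osteoblast_fn,37.155
osteoblast_fn,25.745
osteoblast_fn,53.852
osteoblast_fn,-1.095
osteoblast_fn,17.55
osteoblast_fn,-3
osteoblast_fn,17.493
osteoblast_fn,-8.511
osteoblast_fn,50.281
osteoblast_fn,-10.869
osteoblast_fn,15.784
osteoblast_fn,41.024
osteoblast_fn,29.996
osteoblast_fn,29.092
osteoblast_fn,9.346
osteoblast_fn,25.743
osteoblast_fn,22.166
osteoblast_fn,28.573
osteoblast_fn,48.596
osteoblast_fn,10.294
osteoblast_fn,23.535
osteoblast_fn,25.717
osteoblast_fn,-5.467
osteoblast_fn,26.165
osteoblast_fn,40.809
osteoblast_fn,17.806
osteoblast_fn,1.612
osteoblast_fn,16.869
osteoblast_fn,24.163
osteoblast_fn,-8.252
osteoblast_fn,11.803
osteoblast_fn,20.537
osteoblast_fn,-1.956
osteoblast_fn,3.264
osteoblast_fn,44.198
osteoblast_fn,-5.142
osteoblast_fn,31.736
osteoblast_fn,21.693
osteoblast_fn,20.613
osteoblast_fn,14.936
osteoblast_fn,44.309
osteoblast_fn,30.879
osteoblast_fn,23.883
osteoblast_fn,25.444
osteoblast_fn,25.668
osteoblast_fn,19.278
osteoblast_fn,31.399
osteoblast_fn,58.681
osteoblast_fn,22.987
osteoblast_fn,16.792
osteoblast_fn,36.158
osteoblast_fn,35.656
osteoblast_fn,45.26
osteoblast_fn,-13.87
osteoblast_fn,15.875
osteoblast_fn,22.11
osteoblast_fn,23.916
osteoblast_fn,-6.434
osteoblast_fn,23.195
osteoblast_fn,26.669
osteoblast_fn,-11.071
osteoblast_fn,34.423
osteoblast_fn,14.447
osteoblast_fn,7.04
osteoblast_fn,4.954
osteoblast_fn,26.365
osteoblast_fn,29.849
osteoblast_fn,2.529
osteoblast_fn,32.978
osteoblast_fn,26.628
osteoblast_fn,23.82
osteoblast_fn,30.353
osteoblast_fn,48.853
osteoblast_fn,12.196
myoblast_vn_bmp2,2.796
myoblast_vn_bmp2,32.165
myoblast_vn_bmp2,8.571
myoblast_vn_bmp2,17.757
myoblast_vn_bmp2,21.74
myoblast_vn_bmp2,30.076
myoblast_vn_bmp2,46.723
myoblast_vn_bmp2,-4.099
myoblast_vn_bmp2,28.483
myoblast_vn_bmp2,58.828
myoblast_vn_bmp2,-6.127
myoblast_vn_bmp2,12.931
myoblast_vn_bmp2,-3.119
myoblast_vn_bmp2,5.491
myoblast_vn_bmp2,-39.325
myoblast_vn_bmp2,-27.517
myoblast_vn_bmp2,7.136
myoblast_vn_bmp2,10.473
myoblast_vn_bmp2,15.571
myoblast_vn_bmp2,1.658
myoblast_vn_bmp2,8.982
myoblast_vn_bmp2,-4.394
myoblast_vn_bmp2,39.375
myoblast_vn_bmp2,14.497
myoblast_vn_bmp2,-1.971
myoblast_vn_bmp2,4.778
myoblast_vn_bmp2,14.552
myoblast_vn_bmp2,4.431
myoblast_vn_bmp2,-30.215
myoblast_vn_bmp2,-76.555
myoblast_vn_bmp2,8.089
myoblast_vn_bmp2,35.522
myoblast_vn_bmp2,5.536
myoblast_vn_bmp2,-0.389
myoblast_vn_bmp2,-11.537
myoblast_vn_bmp2,-42.762
myoblast_vn_bmp2,-14.871
myoblast_vn_bmp2,3.921
myoblast_vn_bmp2,51.015
myoblast_vn_bmp2,13.378
myoblast_vn_bmp2,-3.17
myoblast_vn_bmp2,29.057
myoblast_vn_bmp2,16.413
myoblast_vn_bmp2,-7.374
myoblast_vn_bmp2,-73.871
myoblast_vn_bmp2,14.467
myoblast_vn_bmp2,-22.076
myoblast_vn_bmp2,7.029
myoblast_vn_bmp2,-20.978
myoblast_vn_bmp2,14.255
myoblast_vn_bmp2,17.425
myoblast_vn_bmp2,8.758
myoblast_vn_bmp2,19.82
myoblast_vn_bmp2,18.002
myoblast_vn_bmp2,-87.239
myoblast_vn_bmp2,-2.509
myoblast_vn_bmp2,-15.23
myoblast_vn_bmp2,4.078
myoblast_vn_bmp2,21.289
myoblast_vn_bmp2,-3.62
myoblast_vn_bmp2,19.183
myoblast_vn_bmp2,15.168
myoblast_vn_bmp2,8.164
myoblast_vn_bmp2,6.801
myoblast_vn_bmp2,-20.631
myoblast_vn_bmp2,45.525
myoblast_vn_bmp2,10.783
myoblast_vn_bmp2,36.323
myoblast_vn_bmp2,0.185
myoblast_vn_bmp2,22.515
myoblast_vn_bmp2,-55.722
myoblast_vn_bmp2,8.789
myoblast_vn_bmp2,-12.042
myoblast_vn_bmp2,32.552
myoblast_vn_bmp2,11.509
myoblast_vn_bmp2,30.782
myoblast_vn_bmp2,-6.124
myoblast_vn_bmp2,-7.661
myoblast_vn_bmp2,27.948
myoblast_vn_bmp2,-0.184
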