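ratio
0.0138
0.0365
0.0372
0.0385
0.0385
0.0435
0.0457
0.0476
0.0476
0.0537
0.0561
0.0562
0.0673
0.0769
0.0777
0.0802
0.0864
0.0870
0.0894
0.0942
0.1041
0.1053
0.1071
0.1119
0.1149
0.1154
0.1176
0.1180
0.1221
0.1227
0.1253
0.1264
0.1297
0.1302
0.1311
0.1319
0.1369
0.1375
0.1387
0.1390
0.1398
0.1408
0.1417
0.1421
0.1443
0.1456
0.1491
0.1493
0.1520
0.1522
0.1548
0.1593
0.1597
0.1619
0.1620
0.1628
0.1641
0.1646
0.1666
0.1686
0.1730
0.1749
0.1754
0.1761
0.1767
0.1779
0.1789
0.1791
0.1827
0.1831
0.1856
0.1915
0.1956
0.1957
0.1965
0.1987
0.1993
0.1994
0.1994
0.2003
0.2012
0.2032
0.2057
0.2070
0.2113
0.2148
0.2167
0.2190
0.2195
0.2195
0.2196
0.2212
0.2254
0.2321
0.2406
0.2421
0.2430
0.2495
0.2555
0.2641
0.2667
0.2668
0.2690
0.2792
0.3067
0.3067
0.3176
0.3371
0.3436
0.3515
0.4972
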