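"x_um","y_um"
2450,2300
2463.6,2307.8
2476.7,2316.8
2489.3,2327.1
2501.3,2338.7
2512.6,2351.4
2523.2,2365.3
2532.8,2380.3
2541.5,2396.3
2549.2,2413.3
2555.8,2431.3
2561.2,2450.1
2565.4,2469.7
2568.3,2490.1
2569.8,2511.1
2569.9,2532.6
2568.5,2554.6
2565.7,2576.9
2561.3,2599.6
2555.3,2622.4
2547.8,2645.3
2538.6,2668.2
2527.8,2691
2515.4,2713.6
2501.3,2735.8
2485.6,2757.6
2468.2,2778.9
2449.3,2799.5
2428.8,2819.3
2406.7,2838.3
2383.1,2856.4
2358,2873.4
2331.5,2889.2
2303.6,2903.8
2274.4,2917
2243.9,2928.8
2212.3,2939.1
2179.6,2947.7
2145.9,2954.7
2111.3,2959.9
2075.8,2963.2
2039.6,2964.6
2002.8,2964.1
1965.4,2961.5
1927.6,2956.9
1889.6,2950.1
1851.3,2941.2
1813,2930.1
1774.8,2916.8
1736.8,2901.2
1699,2883.4
1661.7,2863.4
1625,2841.1
1589,2816.6
1553.8,2789.8
1519.6,2760.9
1486.5,2729.8
1454.6,2696.6
1424,2661.3
1394.9,2624
1367.4,2584.8
1341.6,2543.6
1317.7,2500.7
1295.7,2456
1275.7,2409.7
1258,2361.8
1242.5,2312.5
1229.3,2261.9
1218.6,2210.1
1210.5,2157.1
1204.9,2103.2
1202.1,2048.4
1202,1993
1204.7,1936.9
1210.3,1880.5
1218.9,1823.8
1230.3,1766.9
1244.8,1710.1
1262.3,1653.5
1282.8,1597.2
1306.3,1541.4
1332.9,1486.3
1362.4,1432
1395,1378.8
1430.5,1326.6
1469,1275.8
1510.3,1226.5
1554.5,1178.8
1601.4,1133
1651,1089
1703.2,1047.2
1757.9,1007.7
1815.1,970.5
1874.6,935.9
1936.3,903.9
2000,874.8
2065.7,848.6
2133.2,825.5
2202.4,805.5
2273.1,788.8
2345.2,775.5
2418.5,765.6
2492.8,759.3
2567.9,756.6
2643.8,757.7
2720.1,762.4
2796.8,771
2873.6,783.4
2950.3,799.7
3026.8,819.8
3102.7,843.9
3178.1,871.9
3252.5,903.8
3325.9,939.5
3398,979.1
3468.7,1022.5
3537.7,1069.6
3604.8,1120.4
3669.9,1174.9
3732.7,1232.9
3793.1,1294.3
3850.9,1359.1
3905.8,1427.1
3957.8,1498.2
4006.6,1572.3
4052,1649.2
4094,1728.8
4132.4,1811
4166.9,1895.5
4197.6,1982.1
4224.1,2070.8
4246.6,2161.3
4264.7,2253.4
4278.4,2346.9
4287.7,2441.6
4292.4,2537.3
4292.5,2633.8
4287.9,2730.8
4278.5,2828
4264.4,2925.4
4245.4,3022.6
4221.6,3119.4
4193,3215.6
4159.5,3310.8
4121.3,3405
4078.3,3497.8
4030.5,3588.9
3978.1,3678.2
3921.1,3765.4
3859.6,3850.3
3793.6,3932.7
3723.3,4012.2
3648.8,4088.7
3570.3,4162
3487.8,4231.9
3401.5,4298
3311.6,4360.3
3218.3,4418.6
3121.7,4472.6
3022,4522.2
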