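"plate_id","well","compound_id","dose_uM","channel","signal"
"imaging_2d_P01","E3","C0007",5,"nuclei_count",1214.89
"imaging_2d_P01","F3","C0007",2.5,"nuclei_count",1199.24
"imaging_2d_P01","G3","C0007",1.25,"nuclei_count",1205.56
"imaging_2d_P01","H3","C0004",5,"nuclei_count",1147.77
"imaging_2d_P01","I3","C0004",2.5,"nuclei_count",1253.76
"imaging_2d_P01","J3","C0004",1.25,"nuclei_count",1322.43
"imaging_2d_P01","K3","C0001",5,"nuclei_count",810.78
"imaging_2d_P01","L3","C0001",2.5,"nuclei_count",802.44
"imaging_2d_P01","M3","C0001",1.25,"nuclei_count",819.56
"imaging_2d_P01","N3","C0005",5,"nuclei_count",1229.17
"imaging_2d_P01","O3","C0005",2.5,"nuclei_count",1210.67
"imaging_2d_P01","P3","C0005",1.25,"nuclei_count",1257.45
"imaging_2d_P01","A4","C0002",5,"nuclei_count",795.5
"imaging_2d_P01","B4","C0002",2.5,"nuclei_count",760.91
"imaging_2d_P01","C4","C0002",1.25,"nuclei_count",752.28
"imaging_2d_P01","D4","C0008",5,"nuclei_count",1199.53
"imaging_2d_P01","E4","C0008",2.5,"nuclei_count",1268.75
"imaging_2d_P01","F4","C0008",1.25,"nuclei_count",1245.38
"imaging_2d_P01","G4","C0003",5,"nuclei_count",1268.19
"imaging_2d_P01","H4","C0003",2.5,"nuclei_count",1266.01
"imaging_2d_P01","I4","C0003",1.25,"nuclei_count",1270.81
"imaging_2d_P01","J4","C0006",5,"nuclei_count",1319.14
"imaging_2d_P01","K4","C0006",2.5,"nuclei_count",1233.5
"imaging_2d_P01","L4","C0006",1.25,"nuclei_count",1274.98
"imaging_2d_P01","A1","",0,"nuclei_count",1267.66
"imaging_2d_P01","B1","",0,"nuclei_count",1291.87
"imaging_2d_P01","C1","",0,"nuclei_count",1173.73
"imaging_2d_P01","D1","",0,"nuclei_count",1232.3
"imaging_2d_P01","E1","",0,"nuclei_count",1196.14
"imaging_2d_P01","F1","",0,"nuclei_count",1196.71
"imaging_2d_P01","G1","",0,"nuclei_count",1214.64
"imaging_2d_P01","H1","",0,"nuclei_count",1196.31
"imaging_2d_P01","I1","",0,"nuclei_count",1155.23
"imaging_2d_P01","J1","",0,"nuclei_count",1285.64
"imaging_2d_P01","K1","",0,"nuclei_count",1180.3
"imaging_2d_P01","L1","",0,"nuclei_count",1243.89
"imaging_2d_P01","M1","",0,"nuclei_count",1235.45
"imaging_2d_P01","N1","",0,"nuclei_count",1169.95
"imaging_2d_P01","O1","",0,"nuclei_count",998.74
"imaging_2d_P01","P1","",0,"nuclei_count",979.54
"imaging_2d_P01","A2","",0,"nuclei_count",951.09
"imaging_2d_P01","B2","",0,"nuclei_count",916.02
"imaging_2d_P01","C2","",0,"nuclei_count",922.39
"imaging_2d_P01","D2","",0,"nuclei_count",979.73
"imaging_2d_P01","E2","",0,"nuclei_count",977.64
"imaging_2d_P01","F2","",0,"nuclei_count",949.84
"imaging_2d_P01","G2","",0,"nuclei_count",1099.17
"imaging_2d_P01","H2","",0,"nuclei_count",977.48
"imaging_2d_P01","I2","",0,"nuclei_count",1050.64
"imaging_2d_P01","J2","",0,"nuclei_count",1013.21
"imaging_2d_P01","K2","",0,"nuclei_count",1048.62
"imaging_2d_P01","L2","",0,"nuclei_count",1019.15
"imaging_2d_P01","M2","",0,"nuclei_count",19.56
"imaging_2d_P01","N2","",0,"nuclei_count",20.3
"imaging_2d_P01","O2","",0,"nuclei_count",20.07
"imaging_2d_P01","P2","",0,"nuclei_count",19.68
"imaging_2d_P01","A3","",0,"nuclei_count",20.15
"imaging_2d_P01","B3","",0,"nuclei_count",18.81
"imaging_2d_P01","C3","",0,"nuclei_count",19.86
"imaging_2d_P01","D3","",0,"nuclei_count",20.85
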