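"plate_id","well","role","compound_id","dose_uM"
"imaging_2d_P01","E3","treated","C0007",5
"imaging_2d_P01","F3","treated","C0007",2.5
"imaging_2d_P01","G3","treated","C0007",1.25
"imaging_2d_P01","H3","treated","C0004",5
"imaging_2d_P01","I3","treated","C0004",2.5
"imaging_2d_P01","J3","treated","C0004",1.25
"imaging_2d_P01","K3","treated","C0001",5
"imaging_2d_P01","L3","treated","C0001",2.5
"imaging_2d_P01","M3","treated","C0001",1.25
"imaging_2d_P01","N3","treated","C0005",5
"imaging_2d_P01","O3","treated","C0005",2.5
"imaging_2d_P01","P3","treated","C0005",1.25
"imaging_2d_P01","A4","treated","C0002",5
"imaging_2d_P01","B4","treated","C0002",2.5
"imaging_2d_P01","C4","treated","C0002",1.25
"imaging_2d_P01","D4","treated","C0008",5
"imaging_2d_P01","E4","treated","C0008",2.5
"imaging_2d_P01","F4","treated","C0008",1.25
"imaging_2d_P01","G4","treated","C0003",5
"imaging_2d_P01","H4","treated","C0003",2.5
"imaging_2d_P01","I4","treated","C0003",1.25
"imaging_2d_P01","J4","treated","C0006",5
"imaging_2d_P01","K4","treated","C0006",2.5
"imaging_2d_P01","L4","treated","C0006",1.25
"imaging_2d_P01","A1","negative_dmso","",0
"imaging_2d_P01","B1","negative_dmso","",0
"imaging_2d_P01","C1","negative_dmso","",0
"imaging_2d_P01","D1","negative_dmso","",0
"imaging_2d_P01","E1","negative_dmso","",0
"imaging_2d_P01","F1","negative_dmso","",0
"imaging_2d_P01","G1","negative_dmso","",0
"imaging_2d_P01","H1","negative_dmso","",0
"imaging_2d_P01","I1","negative_dmso","",0
"imaging_2d_P01","J1","negative_dmso","",0
"imaging_2d_P01","K1","negative_dmso","",0
"imaging_2d_P01","L1","negative_dmso","",0
"imaging_2d_P01","M1","negative_dmso","",0
"imaging_2d_P01","N1","negative_dmso","",0
"imaging_2d_P01","O1","proliferation_hydroxyurea","",0
"imaging_2d_P01","P1","proliferation_hydroxyurea","",0
"imaging_2d_P01","A2","proliferation_hydroxyurea","",0
"imaging_2d_P01","B2","proliferation_hydroxyurea","",0
"imaging_2d_P01","C2","proliferation_hydroxyurea","",0
"imaging_2d_P01","D2","proliferation_hydroxyurea","",0
"imaging_2d_P01","E2","proliferation_hydroxyurea","",0
"imaging_2d_P01","F2","proliferation_hydroxyurea","",0
"imaging_2d_P01","G2","proliferation_hydroxyurea","",0
"imaging_2d_P01","H2","proliferation_hydroxyurea","",0
"imaging_2d_P01","I2","proliferation_hydroxyurea","",0
"imaging_2d_P01","J2","proliferation_hydroxyurea","",0
"imaging_2d_P01","K2","proliferation_hydroxyurea","",0
"imaging_2d_P01","L2","proliferation_hydroxyurea","",0
"imaging_2d_P01","M2","positive_staurosporine","",0
"imaging_2d_P01","N2","positive_staurosporine","",0
"imaging_2d_P01","O2","positive_staurosporine","",0
"imaging_2d_P01","P2","positive_staurosporine","",0
"imaging_2d_P01","A3","positive_staurosporine","",0
"imaging_2d_P01","B3","positive_staurosporine","",0
"imaging_2d_P01","C3","positive_staurosporine","",0
"imaging_2d_P01","D3","positive_staurosporine","",0
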