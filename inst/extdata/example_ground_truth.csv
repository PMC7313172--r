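"compound_id","gr_inf","gec50","hill","shift_enzymatic_2d","shift_imaging_2d","shift_imaging_3d","planted_hit"
"C0007",1,1,1,1,1,1,FALSE
"C0004",0.387533288204577,7.19628345963926,2.29778062913101,1,1,1,FALSE
"C0001",-0.53833728042664,0.00646800695490255,2.28349103778601,1,1,1,TRUE
"C0005",1,1,1,1,1,1,FALSE
"C0002",-0.528316064015962,0.00184698082601617,2.03819189826027,1,1,1,TRUE
"C0008",1,1,1,1,1,1,FALSE
"C0003",0.778782404516823,6.0918885444047,1.6443544406211,1,1,1,FALSE
"C0006",1,1,1,1,1,1,FALSE
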