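species,code,metabolite,compound_class,mean_pct,sd_pct
Amomum koenigii,A,Linalool,Monoterpenes,1.9096,0.1795
Amomum koenigii,A,Camphene,Monoterpenes,1.5867,0.5335
Amomum koenigii,A,(-)-Camphor,Monoterpenes,1.1778,0.2981
Amomum koenigii,A,Borneol,Monoterpenes,1.0792,0.4300
Amomum koenigii,A,Limonene,Monoterpenes,1.0783,0.7768
Amomum koenigii,A,alpha-Pinene,Monoterpenes,0.9384,0.1091
Amomum kravanh,B,"1,8-Cineole",Monoterpenes,8.6057,2.3572
Amomum kravanh,B,beta-Selinene,Sesquiterpenes,3.3511,0.2210
Amomum kravanh,B,alpha-Pinene,Monoterpenes,2.6347,0.4049
Amomum kravanh,B,(-)-beta-Pinene,Monoterpenes,2.3827,1.7027
Amomum kravanh,B,Sabinene,Monoterpenes,2.0574,0.2369
Amomum kravanh,B,beta-Myrcene,Monoterpenes,1.6901,1.2053
Amomum longiligulare,C,Borneol,Monoterpenes,1.4594,1.1597
Amomum longiligulare,C,Camphene,Monoterpenes,1.4351,0.3747
Amomum longiligulare,C,beta-Myrcene,Monoterpenes,1.2737,0.9165
Amomum longiligulare,C,Limonene,Monoterpenes,0.9416,1.0558
Amomum longiligulare,C,Linalool,Monoterpenes,0.8842,0.2345
Amomum longiligulare,C,Caryophyllene,Sesquiterpenes,0.8372,0.4591
Amomum tsaoko,D,"1,8-Cineole",Monoterpenes,8.6216,1.8458
Amomum tsaoko,D,gamma-Muurolene,Sesquiterpenes,3.0686,1.3184
Amomum tsaoko,D,Limonene,Monoterpenes,2.4858,1.9670
Amomum tsaoko,D,Linalool,Monoterpenes,2.4640,1.2840
Amomum tsaoko,D,Copaene,Sesquiterpenes,2.2274,0.6573
Amomum tsaoko,D,Geraniol,Monoterpenes,1.5468,1.6610
Amomum villosum,E,Linalool,Monoterpenes,2.0851,0.6833
Amomum villosum,E,(-)-beta-Pinene,Monoterpenes,1.7271,1.2663
Amomum villosum,E,alpha-Pinene,Monoterpenes,1.3186,0.3246
Amomum villosum,E,Borneol,Monoterpenes,0.7760,1.0974
Amomum villosum,E,beta-Myrcene,Monoterpenes,0.7023,0.9932
Amomum villosum,E,Copaene,Monoterpenes,0.6476,0.9159
Amomum maximum,F,(-)-beta-Pinene,Monoterpenes,2.4277,0.1931
Amomum maximum,F,beta-Selinene,Sesquiterpenes,1.4536,0.1007
Amomum maximum,F,Copaene,Sesquiterpenes,1.2216,0.0431
Amomum maximum,F,beta-Bourbonene,Sesquiterpenes,1.2136,0.1201
Amomum maximum,F,alpha-Ocimene,Monoterpenes,1.1048,0.7753
Amomum maximum,F,Humulene,Sesquiterpenes,0.9789,0.6923
Amomum paratsaoko,G,(Z)-2-Decenal,Aldehydes,1.4423,0.5351
Amomum paratsaoko,G,Octanal,Aldehydes,1.1835,0.6240
Amomum paratsaoko,G,(E)-2-Octenal,Aldehydes,1.0320,0.4831
Amomum paratsaoko,G,Limonene,Monoterpenes,0.9243,0.2577
Amomum paratsaoko,G,alpha-Pinene,Monoterpenes,0.8682,0.0838
Amomum paratsaoko,G,alpha-Ocimene,Monoterpenes,0.7899,0.1907
Alpinia galanga,H,Caryophyllene,Sesquiterpenes,2.1802,1.5630
Alpinia galanga,H,Tridecane,Hydrocarbons,1.9142,0.3532
Alpinia galanga,H,Decyl acetate,Esters,1.5508,0.5689
Alpinia galanga,H,Copaene,Sesquiterpenes,1.3953,0.1010
Alpinia galanga,H,Alloaromadendrene,Sesquiterpenes,1.3661,0.0971
Alpinia galanga,H,"1,8-Cineole",Monoterpenes,1.3611,0.4756
Alpinia katsumadai,I,Estragole,Monoterpenes,1.3972,0.3235
Alpinia katsumadai,I,Acetic acid,Acids,0.2495,0.1786
Alpinia katsumadai,I,(-)-beta-Pinene,Monoterpenes,0.2406,0.1470
Alpinia katsumadai,I,o-Cymene,Hydrocarbons,0.2366,0.1923
Alpinia katsumadai,I,"1,8-Cineole",Monoterpenes,0.1577,0.0265
Alpinia katsumadai,I,Limonene,Monoterpenes,0.1514,0.0243
Alpinia zerumbet,J,"1,8-Cineole",Monoterpenes,2.4631,0.9457
Alpinia zerumbet,J,Linalool,Monoterpenes,2.2433,0.2904
Alpinia zerumbet,J,Limonene,Monoterpenes,1.9982,1.1538
Alpinia zerumbet,J,o-Cymene,Hydrocarbons,1.7801,1.2708
Alpinia zerumbet,J,alpha-Pinene,Monoterpenes,1.4746,0.2429
Alpinia zerumbet,J,Borneol,Monoterpenes,1.4343,1.0396
Alpinia japonica,K,"1,8-Cineole",Monoterpenes,1.8123,0.1452
Alpinia japonica,K,Methyl hexanoate,Esters,0.7849,0.1505
Alpinia japonica,K,Linalool,Monoterpenes,0.6186,0.1141
Alpinia japonica,K,o-Cymene,Hydrocarbons,0.5333,0.0981
Alpinia japonica,K,alpha-Terpineol,Monoterpenes,0.4864,0.0370
Alpinia japonica,K,(-)-beta-Pinene,Monoterpenes,0.4055,0.0520
Alpinia oxyphylla,L,Citral,Monoterpenes,3.1651,2.6423
Alpinia oxyphylla,L,Humulene,Sesquiterpenes,1.6426,1.1672
Alpinia oxyphylla,L,(-)-beta-Pinene,Monoterpenes,1.5048,0.7049
Alpinia oxyphylla,L,alpha-Ocimene,Monoterpenes,1.4872,0.8404
Alpinia oxyphylla,L,Linalool,Monoterpenes,1.4704,0.1282
Alpinia oxyphylla,L,beta-Myrcene,Monoterpenes,1.4372,0.1290
Zingiber striolatum,M,Linalool,Monoterpenes,0.6799,0.3538
Zingiber striolatum,M,(-)-Bornyl acetate,Monoterpenes,0.5004,0.0663
Zingiber striolatum,M,Camphene,Monoterpenes,0.3450,0.1443
Zingiber striolatum,M,Acetic acid,Acids,0.2345,0.0430
Zingiber striolatum,M,"1,8-Cineole",Monoterpenes,0.2029,0.0813
Zingiber striolatum,M,Copaene,Sesquiterpenes,0.1585,0.0688
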