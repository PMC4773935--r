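sex,site,observed,m1A,m1B,m2,m3,m4,m5,m6,m7,m8,m9
male,Head and neck (C00-14),324,279,288,287,306,246,221,292,298,291,335
male,Oesophagus (C15),168,159,160,154,181,170,182,146,166,155,217
male,Stomach (C16),293,296,294,355,281,269,276,431,296,238,297
male,Colon-rectum (C18-21),1948,1947,1882,1895,1834,1668,1994,2083,1797,1617,1428
male,Liver (C22),120,105,98,94,100,99,112,91,94,113,193
male,Gallbladder (C23-24),73,76,64,67,43,25,28,68,71,60,89
male,Pancreas (C25),332,377,385,352,376,309,367,343,355,281,329
male,Larynx (C32),97,89,82,107,113,112,119,110,113,83,104
male,Lung (C33-34),1561,1554,1617,1579,1494,1338,1439,1654,1549,1357,1357
male,Melanoma of skin (C43),773,616,672,592,669,726,815,503,646,741,578
male,Prostate (C61),4533,5414,5487,4302,4165,3897,8741,4397,4286,3805,3815
male,Testis (C62),288,299,303,272,229,230,172,282,256,232,185
male,Kidney (C64-66),484,463,452,407,404,296,418,405,406,428,400
male,Bladder (C67),938,1045,1050,1000,1071,843,1078,1060,956,809,924
male,Brain (C70-72),518,628,625,530,562,368,563,527,515,452,412
male,Thyroid (C73),77,80,87,67,38,38,70,61,71,65,87
male,Hodgkin lymphoma (C81),73,94,73,76,54,47,45,63,80,62,63
male,"Non-Hodgkin lymphoma (C82-85, C96)",499,483,485,451,426,391,444,420,473,441,455
male,"Multiple myeloma (C88, C90)",218,210,211,202,186,169,216,187,209,194,162
male,Leukaemia (C91-95),363,339,344,336,310,292,403,290,361,368,313
male,Other and unspecified,827,858,867,829,662,569,759,826,845,752,839
female,Head and neck (C00-14),188,174,187,163,165,136,157,155,174,192,185
female,Oesophagus (C15),58,62,56,56,56,56,61,53,64,54,85
female,Stomach (C16),196,201,218,230,210,188,209,280,200,151,197
female,Colon-rectum (C18-21),1894,1939,1947,1856,1732,1647,2217,1961,1781,1671,1309
female,Liver (C22),73,49,59,49,74,65,86,54,48,63,94
female,Gallbladder (C23-24),84,83,85,80,44,23,34,72,79,75,96
female,Pancreas (C25),358,363,369,355,361,286,367,342,348,303,331
female,Larynx (C32),18,10,14,15,17,18,19,14,18,19,21
female,Lung (C33-34),1210,1197,1328,1042,1172,1026,1118,965,1095,1173,1171
female,Melanoma of skin (C43),797,698,707,630,936,1068,1591,557,675,793,646
female,Breast (C50),2891,3059,2896,2958,2672,2550,4540,2818,3062,2772,3651
female,Cervix (C53),307,285,296,310,282,234,338,330,312,286,250
female,Corpus uteri (C54),744,801,763,715,639,632,691,721,740,721,599
female,Ovary (C56),479,432,462,489,451,445,559,477,509,457,392
female,Kidney (C64-66),246,269,272,237,215,140,263,232,229,216,243
female,Bladder (C67),359,378,326,349,351,321,438,353,347,329,306
female,Brain (C70-72),629,903,858,688,663,407,788,672,672,542,459
female,Thyroid (C73),206,184,176,163,189,181,236,177,152,206,242
female,Hodgkin lymphoma (C81),57,56,54,51,25,23,39,56,50,54,54
female,"Non-Hodgkin lymphoma (C82-85, C96)",412,398,390,374,292,274,436,371,369,381,385
female,"Multiple myeloma (C88, C90)",159,164,164,162,126,130,207,151,171,151,129
female,Leukaemia (C91-95),272,260,253,248,216,197,307,223,265,276,218
female,Other and unspecified,829,910,857,855,762,726,921,807,886,767,876
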