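sex,site,m1A,m1B,m2,m3,m4,m5,m6,m7,m8,m9
male,Head and neck (C00-14),-13.9,-11.1,-11.4,-5.6,-24.1,-31.8,-9.9,-8.0,-10.2,3.4
male,Oesophagus (C15),-5.4,-4.8,-8.3,7.7,1.2,8.3,-13.1,-1.2,-7.7,29.2
male,Stomach (C16),1.0,0.3,21.2,-4.1,-8.2,-5.8,47.1,1.0,-18.8,1.4
male,Colon-rectum (C18-21),0.0,-3.4,-2.7,-5.8,-14.4,2.4,6.9,-7.8,-17.0,-26.7
male,Liver (C22),-12.5,-18.3,-21.7,-16.7,-17.5,-6.7,-24.2,-21.7,-5.8,60.8
male,Gallbladder (C23-24),4.1,-12.3,-8.2,-41.1,-65.8,-61.6,-6.8,-2.7,-17.8,21.9
male,Pancreas (C25),13.6,16.0,6.0,13.3,-6.9,10.5,3.3,6.9,-15.4,-0.9
male,Larynx (C32),-8.3,-15.5,10.3,16.5,15.5,22.7,13.4,16.5,-14.4,7.2
male,Lung (C33-34),-0.5,3.6,1.2,-4.3,-14.3,-7.8,6.0,-0.8,-13.1,-13.1
male,Melanoma of skin (C43),-20.3,-13.1,-23.4,-13.5,-6.1,5.4,-34.9,-16.4,-4.1,-25.2
male,Prostate (C61),19.4,21.1,-5.1,-8.1,-14.0,92.8,-3.0,-5.5,-16.1,-15.8
male,Testis (C62),3.8,5.2,-5.6,-20.5,-20.1,-40.3,-2.1,-11.1,-19.4,-35.8
male,Kidney (C64-66),-4.3,-6.6,-15.9,-16.5,-38.8,-13.6,-16.3,-16.1,-11.6,-17.4
male,Bladder (C67),11.4,11.9,6.6,14.2,-10.1,14.9,13.0,1.9,-13.8,-1.5
male,Brain (C70-72),21.2,20.7,2.3,8.5,-29.0,8.7,1.7,-0.6,-12.7,-20.5
male,Thyroid (C73),3.9,13.0,-13.0,-50.7,-50.7,-9.1,-20.8,-7.8,-15.6,13.0
male,Hodgkin lymphoma (C81),28.8,0.0,4.1,-26.0,-35.6,-38.4,-13.7,9.6,-15.1,-13.7
male,"Non-Hodgkin lymphoma (C82-85, C96)",-3.2,-2.8,-9.6,-14.6,-21.6,-11.0,-15.8,-5.2,-11.6,-8.8
male,"Multiple myeloma (C88, C90)",-3.7,-3.2,-7.3,-14.7,-22.5,-0.9,-14.2,-4.1,-11.0,-25.7
male,Leukaemia (C91-95),-6.6,-5.2,-7.4,-14.6,-19.6,11.0,-20.1,-0.5,1.4,-13.8
male,Other and unspecified,3.8,4.8,0.2,-20.0,-31.2,-8.2,-0.1,2.2,-9.1,1.5
female,Head and neck (C00-14),-7.5,-0.5,-3.3,-12.2,-27.7,-16.5,-17.6,-7.5,2.1,-1.6
female,Oesophagus (C15),6.9,-3.5,-3.5,-3.5,-3.5,5.2,-8.6,10.3,-6.9,46.6
female,Stomach (C16),2.6,11.2,17.4,7.1,-4.1,6.6,42.9,2.0,-23.0,0.5
female,Colon-rectum (C18-21),2.4,2.8,-2.0,-8.6,-13.0,17.1,3.5,-6.0,-11.8,-30.9
female,Liver (C22),-32.9,-19.2,-32.9,1.4,-11.0,17.8,-26.0,-34.3,-13.7,28.8
female,Gallbladder (C23-24),-1.2,1.2,-4.8,-47.6,-72.6,-59.5,-14.3,-6.0,-10.7,14.3
female,Pancreas (C25),1.4,3.1,-0.8,0.8,-20.1,2.5,-4.5,-2.8,-15.4,-7.5
female,Larynx (C32),-44.4,-22.2,-16.7,-5.6,0.0,5.6,-22.2,0.0,5.6,16.7
female,Lung (C33-34),-1.1,9.8,-13.9,-3.1,-15.2,-7.6,-20.3,-9.5,-3.1,-3.2
female,Melanoma of skin (C43),-12.4,-11.3,-21.0,17.4,34.0,99.6,-30.1,-15.3,-0.5,-19.0
female,Breast (C50),5.8,0.2,2.3,-7.6,-11.8,57.0,-2.5,5.9,-4.1,26.3
female,Cervix (C53),-7.2,-3.6,1.0,-8.1,-23.8,10.1,7.5,1.6,-6.8,-18.6
female,Corpus uteri (C54),7.7,2.6,-3.9,-14.1,-15.1,-7.1,-3.1,-0.5,-3.1,-19.5
female,Ovary (C56),-9.8,-3.6,2.1,-5.8,-7.1,16.7,-0.4,6.3,-4.6,-18.2
female,Kidney (C64-66),9.3,10.6,-3.7,-12.6,-43.1,6.9,-5.7,-6.9,-12.2,-1.2
female,Bladder (C67),5.3,-9.2,-2.8,-2.2,-10.6,22.0,-1.7,-3.3,-8.4,-14.8
female,Brain (C70-72),43.6,36.4,9.4,5.4,-35.3,25.3,6.8,6.8,-13.8,-27.0
female,Thyroid (C73),-10.7,-14.6,-20.9,-8.3,-12.1,14.6,-14.1,-26.2,0.0,17.5
female,Hodgkin lymphoma (C81),-1.8,-5.3,-10.5,-56.1,-59.7,-31.6,-1.8,-12.3,-5.3,-5.3
female,"Non-Hodgkin lymphoma (C82-85, C96)",-3.4,-5.3,-9.2,-29.1,-33.5,5.8,-10.0,-10.4,-7.5,-6.6
female,"Multiple myeloma (C88, C90)",3.1,3.1,1.9,-20.8,-18.2,30.2,-5.0,7.6,-5.0,-18.9
female,Leukaemia (C91-95),-4.4,-7.0,-8.8,-20.6,-27.6,12.9,-18.0,-2.6,1.5,-19.9
female,Other and unspecified,9.8,3.4,3.1,-8.1,-12.4,11.1,-2.7,6.9,-7.5,5.7
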