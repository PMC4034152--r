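species,context,action,center_cm1,fwhm_cm1,rel_amplitude,shape,assignment
all,core,add,2925,16,0.60,lorentzian,lipid CH2 asymmetric stretch
all,core,add,1515,10,0.40,lorentzian,tyrosine ring (amide II)
all,core,add,1451,12,0.45,lorentzian,lipid CH2/CH3 asymmetric bending
all,core,add,1373,10,0.40,lorentzian,chitin CH3 symmetric deformation
all,core,add,1154,12,0.50,lorentzian,chitin C-O stretch
all,core,add,1031,14,0.80,lorentzian,beta-1-3-glucan C-O stretch
all,core,add,1003,10,0.45,lorentzian,chitin ring vibration
Amanita_rubescens,core,add,1633,16,1.00,lorentzian,amide I beta-sheet
Amanita_rubescens,core,add,1548,10,0.45,lorentzian,amide II alpha-helix
Amanita_rubescens,core,add,1542,10,0.45,lorentzian,amide II alpha-helix
Amanita_rubescens,core,add,1161,12,0.30,lorentzian,glycogen C-O shoulder
Amanita_rubescens,core,add,1090,12,0.35,lorentzian,beta-1-3-glucan shoulder (shifted)
Amanita_rubescens,core,add,1370,10,0.35,lorentzian,lipid carboxylate / CH deformation
Amanita_rubescens,core,add,990,10,0.35,lorentzian,mannan shoulder
Amanita_rubescens,core,add,976,10,0.35,lorentzian,mannan shoulder
Xerocomus_pruinatus,core,add,1630,16,1.00,lorentzian,amide I beta-sheet
Xerocomus_pruinatus,core,add,1548,10,0.45,lorentzian,amide II alpha-helix
Xerocomus_pruinatus,core,add,1542,10,0.45,lorentzian,amide II alpha-helix
Xerocomus_pruinatus,core,add,1161,12,0.30,lorentzian,glycogen C-O shoulder
Xerocomus_pruinatus,core,add,1075,12,0.35,lorentzian,beta-1-3-glucan shoulder
Xerocomus_pruinatus,core,add,990,10,0.35,lorentzian,mannan shoulder
Xerocomus_pruinatus,core,add,976,10,0.35,lorentzian,mannan shoulder
Lactarius_subdulcis,core,add,1632,16,1.00,lorentzian,amide I beta-sheet
Lactarius_subdulcis,core,add,1153,12,0.30,lorentzian,glycogen C-O shoulder
Lactarius_subdulcis,core,add,2850,14,0.50,lorentzian,lipid CH2 symmetric stretch
Lactarius_subdulcis,core,add,1740,14,0.50,lorentzian,lipid ester C=O stretch
Lactarius_subdulcis,core,add,1075,12,0.35,lorentzian,beta-1-3-glucan shoulder
Lactarius_subdulcis,core,add,1370,10,0.35,lorentzian,lipid carboxylate / CH deformation
Lactarius_subdulcis,core,add,990,10,0.35,lorentzian,mannan shoulder
Lactarius_subdulcis,core,add,976,10,0.35,lorentzian,mannan shoulder
Russula_ochroleuca,core,add,1627,16,0.90,lorentzian,amide I beta-sheet
Russula_ochroleuca,core,add,1618,16,0.45,lorentzian,amide I beta-sheet
Russula_ochroleuca,core,add,1649,16,0.60,lorentzian,amide I random coil
Russula_ochroleuca,core,add,1153,12,0.30,lorentzian,glycogen C-O shoulder
Russula_ochroleuca,core,add,2850,14,0.50,lorentzian,lipid CH2 symmetric stretch
Russula_ochroleuca,core,add,1740,14,0.50,lorentzian,lipid ester C=O stretch
Russula_ochroleuca,core,add,1075,12,0.35,lorentzian,beta-1-3-glucan shoulder
Russula_ochroleuca,core,add,1370,10,0.35,lorentzian,lipid carboxylate / CH deformation
Russula_ochroleuca,core,add,990,10,0.35,lorentzian,mannan shoulder
Russula_ochroleuca,core,add,976,10,0.35,lorentzian,mannan shoulder
Cenococcum_geophilum,core,add,1617,16,1.00,lorentzian,amide I beta-sheet (shifted)
Cenococcum_geophilum,core,add,1153,12,0.30,lorentzian,glycogen C-O shoulder
Cenococcum_geophilum,core,add,1108,12,0.80,lorentzian,polysaccharide C-O stretch
Cenococcum_geophilum,core,add,831,10,0.45,lorentzian,mannan marker
Cenococcum_geophilum,core,add,1075,12,0.35,lorentzian,beta-1-3-glucan shoulder
Cenococcum_geophilum,core,add,1370,10,0.35,lorentzian,lipid carboxylate / CH deformation
Cenococcum_geophilum,mono,remove,1451,NA,NA,NA,absent in beech-stand samples
Cenococcum_geophilum,mono,remove,1373,NA,NA,NA,absent in beech-stand samples
Cenococcum_geophilum,mono,remove,1370,NA,NA,NA,absent in beech-stand samples
Cenococcum_geophilum,mono,remove,831,NA,NA,NA,absent in beech-stand samples
Cenococcum_geophilum,mixed,add,2363,12,0.30,lorentzian,mixed-stand supplementary band
Cenococcum_geophilum,mixed,add,1663,14,0.30,lorentzian,mixed-stand supplementary band
Cenococcum_geophilum,mixed,add,1453,10,0.30,lorentzian,protein CH3/CH2 asymmetric bending
Cenococcum_geophilum,mixed,add,1372,10,0.30,lorentzian,protein CH3/CH2 asymmetric bending
Cenococcum_geophilum,mixed,add,830,10,0.30,lorentzian,mixed-stand supplementary band
Cenococcum_geophilum,swabian,add,1621,14,0.30,lorentzian,protein beta-sheet (site band)
Cenococcum_geophilum,swabian,add,1234,12,0.30,lorentzian,asymmetric P-H stretch (site band)
Xerocomus_pruinatus,mixed,add,1313,10,0.30,lorentzian,protein CH3/CH2 asymmetric bending
Amanita_rubescens,mixed,add,1544,10,0.30,lorentzian,amide II alpha-helix (site band)
Amanita_rubescens,mixed,add,1372,10,0.30,lorentzian,protein CH3/CH2 asymmetric bending
Amanita_rubescens,mono,add,1407,10,0.30,lorentzian,beech-stand supplementary band
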