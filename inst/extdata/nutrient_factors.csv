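name,salt,mid_mM,role,baseline
Ca,CaCl2.2H2O,0.213,factor,original
Mg,MgSO4.7H2O,0.375,factor,original
Ca,CaCl2.2H2O,0.85,factor,refined
Mg,MgSO4.7H2O,1.50,factor,refined
Fe,Fe2(SO4)3.7H2O,0.001,factor,both
Mn,MnCl2.H2O,0.0258,factor,both
Cu,CuSO4.5H2O,0.0064,factor,both
Zn,ZnSO4.7H2O,0.077,factor,both
B,H3BO3,0.184,factor,both
Se,Na2SeO3,0.0001,factor,both
V,VOSO4.H2O,0.000009,factor,both
Si,Na2SiO3.5H2O,0.273,factor,both
Mo,(NH4)6MoO4.4H2O,0.00089,constant,both
Co,CoCl2.6H2O,0.0067,constant,both
EDTA,Na2EDTA pH 8.0,0.5373,constant,both
Tris,Tris-HCl pH 7.4,100,constant,both
B1,thiamine hydrochloride,0.052,constant,both
B12,cyanocobalamin,0.0001,constant,both
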