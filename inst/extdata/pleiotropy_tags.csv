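"snp_id","outcome_id","gene_label","source"
"rs2954021","cad_hapmap","TRIB1","cad_mi"
"rs174601","cad_hapmap","C11orf10, FADS1, FADS2","cad_mi"
"rs314253","cad_hapmap","ASGR1, DLG4","cad_mi"
"rs579459","cad_hapmap","ABO","cad_mi"
"rs6984305","cad_hapmap","PPP1R3B","cad_mi"
"rs516246","cad_hapmap","FUT2","cad_mi"
"rs7310409","cad_hapmap","HNF1A","cad_mi"
"rs1260326","cad_hapmap","C2orf16, GCKR","cad_mi"
"rs2954021","cad_1000g","TRIB1","cad_mi"
"rs174601","cad_1000g","C11orf10, FADS1, FADS2","cad_mi"
"rs314253","cad_1000g","ASGR1, DLG4","cad_mi"
"rs579459","cad_1000g","ABO","cad_mi"
"rs6984305","cad_1000g","PPP1R3B","cad_mi"
"rs516246","cad_1000g","FUT2","cad_mi"
"rs7310409","cad_1000g","HNF1A","cad_mi"
"rs1260326","cad_1000g","C2orf16, GCKR","cad_mi"
"rs2954021","t2dm","TRIB1","diabetes"
"rs516246","t2dm","FUT2","diabetes"
"rs1260326","t2dm","C2orf16, GCKR","diabetes"
"rs2954021","ldl","TRIB1","lipids"
"rs174601","ldl","C11orf10, FADS1, FADS2","lipids"
"rs314253","ldl","ASGR1, DLG4","lipids"
"rs579459","ldl","ABO","lipids"
"rs6984305","ldl","PPP1R3B","lipids"
"rs516246","ldl","FUT2","lipids"
"rs7310409","ldl","HNF1A","lipids"
"rs1260326","ldl","C2orf16, GCKR","lipids"
"rs2954021","hdl","TRIB1","lipids"
"rs174601","hdl","C11orf10, FADS1, FADS2","lipids"
"rs314253","hdl","ASGR1, DLG4","lipids"
"rs579459","hdl","ABO","lipids"
"rs6984305","hdl","PPP1R3B","lipids"
"rs516246","hdl","FUT2","lipids"
"rs7310409","hdl","HNF1A","lipids"
"rs1260326","hdl","C2orf16, GCKR","lipids"
"rs2954021","tg","TRIB1","lipids"
"rs174601","tg","C11orf10, FADS1, FADS2","lipids"
"rs314253","tg","ASGR1, DLG4","lipids"
"rs579459","tg","ABO","lipids"
"rs6984305","tg","PPP1R3B","lipids"
"rs516246","tg","FUT2","lipids"
"rs7310409","tg","HNF1A","lipids"
"rs1260326","tg","C2orf16, GCKR","lipids"
"rs2954021","hba1c","TRIB1","glycemic"
"rs516246","hba1c","FUT2","glycemic"
"rs1260326","hba1c","C2orf16, GCKR","glycemic"
"rs2954021","fg","TRIB1","glycemic"
"rs516246","fg","FUT2","glycemic"
"rs1260326","fg","C2orf16, GCKR","glycemic"
"rs2954021","homa_ir","TRIB1","glycemic"
"rs516246","homa_ir","FUT2","glycemic"
"rs1260326","homa_ir","C2orf16, GCKR","glycemic"
"rs2954021","homa_b","TRIB1","glycemic"
"rs516246","homa_b","FUT2","glycemic"
"rs1260326","homa_b","C2orf16, GCKR","glycemic"
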