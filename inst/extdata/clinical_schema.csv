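name,display_name,kind,unit
Age,Age,continuous,years
BMI,BMI,continuous,kg/m2
MenarcheAge,Age of menarche,continuous,years
BRCA1,BRCA 1,binary,
BRCA2,BRCA 2,binary,
CA125,CA-125,continuous,UI/ml
MatoRRSO,MatoRRSO,binary,
PregnancyNftd,Pregnancy nftd,count,
EstroprogestinUse,Estroprogestin use,binary,
Endometriosis,History of endometriosis,binary,
PAPS,PAPS,binary,
PreviousBC,Previous BC,binary,
BC_FDR,BC FDR,binary,
BC_Nfdr,BC Nfdr,count,
BC_SDR,BC SDR,binary,
BC_Nsdr,BC Nsdr,count,
OC_FDR,OC FDR,binary,
OC_Nfdr,OC Nfdr,count,
OC_SDR,OC SDR,binary,
OC_Nsdr,OC Nsdr,count,
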