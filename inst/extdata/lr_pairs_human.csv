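ligand,receptor,annotation
TGFB1,TGFBR1,TGF-beta
TGFB1,TGFBR2,TGF-beta
TGFB2,TGFBR1,TGF-beta
TGFB3,TGFBR2,TGF-beta
INHBA,ACVR1B,TGF-beta
BMP2,BMPR1A,BMP
BMP4,BMPR1A,BMP
BMP7,BMPR2,BMP
WNT5A,MCAM,WNT
WNT5A,ROR1,WNT
WNT5A,ROR2,WNT
WNT5A,FZD2,WNT
WNT5A,FZD5,WNT
WNT3A,FZD1,WNT
SERPINE1,LRP1,protease/clearance
APOE,LRP1,lipoprotein
APOE,LDLR,lipoprotein
SHH,PTCH1,hedgehog
IHH,PTCH1,hedgehog
DLL1,NOTCH1,notch
DLL4,NOTCH1,notch
JAG1,NOTCH1,notch
JAG1,NOTCH2,notch
JAG2,NOTCH1,notch
CXCL12,CXCR4,chemokine
CXCL12,ACKR3,chemokine
CXCL13,CXCR5,chemokine
CXCL1,CXCR2,chemokine
CXCL2,CXCR2,chemokine
CXCL5,CXCR2,chemokine
CXCL8,CXCR1,chemokine
CXCL8,CXCR2,chemokine
CXCL9,CXCR3,chemokine
CXCL10,CXCR3,chemokine
CXCL11,CXCR3,chemokine
CX3CL1,CX3CR1,chemokine
CCL2,CCR2,chemokine
CCL3,CCR1,chemokine
CCL4,CCR5,chemokine
CCL5,CCR5,chemokine
CCL8,CCR2,chemokine
CCL11,CCR3,chemokine
CCL19,CCR7,chemokine
CCL20,CCR6,chemokine
CCL21,CCR7,chemokine
IL1B,IL1R1,interleukin
IL2,IL2RA,interleukin
IL2,IL2RB,interleukin
IL4,IL4R,interleukin
IL6,IL6R,interleukin
IL7,IL7R,interleukin
IL10,IL10RA,interleukin
IL13,IL13RA1,interleukin
IL15,IL15RA,interleukin
IL18,IL18R1,interleukin
IL21,IL21R,interleukin
IL33,IL1RL1,interleukin
TSLP,IL7R,interleukin
TSLP,CRLF2,interleukin
OSM,OSMR,interleukin
LIF,LIFR,interleukin
TNF,TNFRSF1A,TNF
TNF,TNFRSF1B,TNF
LTA,TNFRSF1A,TNF
FASLG,FAS,TNF
TNFSF10,TNFRSF10A,TNF
TNFSF10,TNFRSF10B,TNF
CD40LG,CD40,TNF
CD70,CD27,TNF
TNFSF13B,TNFRSF13B,TNF
ICOSLG,ICOS,checkpoint
CD274,PDCD1,checkpoint
PDCD1LG2,PDCD1,checkpoint
CD80,CTLA4,checkpoint
CD86,CTLA4,checkpoint
CD80,CD28,checkpoint
CD86,CD28,checkpoint
LGALS9,HAVCR2,checkpoint
EGF,EGFR,growth factor
TGFA,EGFR,growth factor
HBEGF,EGFR,growth factor
AREG,EGFR,growth factor
NRG1,ERBB3,growth factor
NRG1,ERBB4,growth factor
IGF1,IGF1R,growth factor
IGF2,IGF1R,growth factor
FGF2,FGFR1,growth factor
FGF7,FGFR2,growth factor
FGF10,FGFR2,growth factor
HGF,MET,growth factor
VEGFA,FLT1,angiogenesis
VEGFA,KDR,angiogenesis
VEGFB,FLT1,angiogenesis
VEGFC,FLT4,angiogenesis
PGF,FLT1,angiogenesis
ANGPT1,TEK,angiogenesis
ANGPT2,TEK,angiogenesis
PDGFA,PDGFRA,growth factor
PDGFB,PDGFRB,growth factor
PDGFC,PDGFRA,growth factor
PDGFD,PDGFRB,growth factor
CSF1,CSF1R,myeloid
CSF2,CSF2RA,myeloid
CSF3,CSF3R,myeloid
KITLG,KIT,growth factor
FLT3LG,FLT3,myeloid
NGF,NTRK1,neurotrophin
BDNF,NTRK2,neurotrophin
FN1,ITGA5,ECM/integrin
FN1,ITGB1,ECM/integrin
FN1,ITGAV,ECM/integrin
COL1A1,ITGA1,ECM/integrin
COL1A1,ITGA2,ECM/integrin
COL1A1,DDR1,ECM/integrin
COL1A2,ITGB1,ECM/integrin
COL4A1,ITGB1,ECM/integrin
LAMB1,ITGB1,ECM/integrin
TNC,ITGB1,ECM/integrin
THBS1,CD47,ECM/integrin
THBS1,CD36,ECM/integrin
SPP1,CD44,ECM/integrin
SPP1,ITGAV,ECM/integrin
SPP1,ITGB3,ECM/integrin
VTN,ITGAV,ECM/integrin
ICAM1,ITGAL,adhesion
ICAM1,ITGB2,adhesion
VCAM1,ITGA4,adhesion
SELP,SELPLG,adhesion
MIF,CD74,cytokine
APP,CD74,amyloid
MDK,NCL,heparin-binding
MDK,SDC1,heparin-binding
PTN,PTPRZ1,heparin-binding
GAS6,AXL,TAM
GAS6,MERTK,TAM
PROS1,AXL,TAM
EFNA1,EPHA2,ephrin
EFNB2,EPHB4,ephrin
SEMA3A,NRP1,semaphorin
SEMA4D,PLXNB1,semaphorin
SLIT2,ROBO1,axon guidance
NTN1,DCC,axon guidance
LGALS1,PTPRC,galectin
ANXA1,FPR1,resolution
ANXA1,FPR2,resolution
C3,C3AR1,complement
C5,C5AR1,complement
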