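name,dsi_group,pasi_pair,source
Picholine,G1,R1R3,stated
Arbequina,G1,R1R3,stated
Cayon,G1,R1R4,stated
Tanche,G2,R2R3,stated
SantaCaterina,G1,R2R3,stated
Manzanilla,G2,R1R2,stated
Leccino,G1,R1R5,stated
Grossane,G1,R1R5,stated
DolceAgogia,G2,R2R3,stated
Frantoio,G1,R4R5,stated
Cailletier,G1,R4R5,stated
Kalamata,G2,R2R4,stated
PicholineMarocaine,G2,R2R4,stated
Bouteillan,G2,R2R4,stated
Koroneiki,G2,R2R6,stated
Salonenque,G1,R3R5,stated
Rosciola,G2,R3R5,stated
Aglandau,G2,R2R5,stated
Amellau,G2,R3R4,stated
Moraiolo,G1,R4R6,stated
IstrskaBelica,G2,R4R6,stated
Barnea,G1,R1R6,stated
Erbano,G2,R4R5,stated
PetitRibier,G1,R4R5,inferred
CayetRoux,G2,R4R5,inferred
Lucques,G2,R2R3,inferred
Oliviere,G2,R2R4,inferred
VerdaleH,G2,R2R4,inferred
VerdaleDeMillas,G2,R2R4,inferred
Cayanne,G1,R4R5,inferred
Clermontaise,G1,R4R5,inferred
Redouneil,G1,R3R5,inferred
Picual,G2,R3R4,inferred
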