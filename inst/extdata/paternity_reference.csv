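host,father,dsi_printed,pasi_printed,dsd_printed,anomaly,note
Aglandau,Frantoio,Accept,Reject,TRUE,FALSE,
Aglandau,PetitRibier,Accept,Reject,TRUE,FALSE,
Aglandau,CayetRoux,Reject,Reject,FALSE,FALSE,
Bouteillan,Aglandau,Reject,Reject,FALSE,FALSE,
Bouteillan,VerdaleH,Reject,Reject,FALSE,FALSE,
Bouteillan,Manzanilla,Reject,Reject,FALSE,FALSE,
Oliviere,Aglandau,Reject,Reject,FALSE,FALSE,
Oliviere,Bouteillan,Reject,Reject,FALSE,FALSE,
Oliviere,VerdaleH,Reject,Reject,FALSE,FALSE,
Oliviere,Manzanilla,Reject,Reject,FALSE,FALSE,
VerdaleH,Aglandau,Reject,Reject,FALSE,FALSE,
VerdaleH,Bouteillan,Reject,Reject,FALSE,FALSE,
VerdaleH,Manzanilla,Reject,Reject,FALSE,FALSE,
VerdaleDeMillas,Aglandau,Reject,Reject,FALSE,FALSE,
VerdaleDeMillas,Bouteillan,Reject,Reject,FALSE,FALSE,
VerdaleDeMillas,VerdaleH,Reject,Reject,FALSE,FALSE,
VerdaleDeMillas,Manzanilla,Reject,Reject,FALSE,FALSE,
Lucques,Aglandau,Reject,Reject,FALSE,FALSE,
Lucques,Bouteillan,Reject,Reject,FALSE,FALSE,
Tanche,Aglandau,Reject,Reject,FALSE,FALSE,
Tanche,Bouteillan,Reject,Reject,FALSE,FALSE,
Lucques,Picholine,Accept,Reject,TRUE,FALSE,
Lucques,Arbequina,Accept,Reject,TRUE,FALSE,
Tanche,Picholine,Accept,Reject,TRUE,FALSE,
Tanche,Arbequina,Accept,Reject,TRUE,FALSE,
CayetRoux,Aglandau,Reject,Accept,TRUE,FALSE,
Grossane,Frantoio,Accept,Reject,FALSE,TRUE,printed stigma verdict conflicts with both parents belonging to G1
Grossane,PetitRibier,Accept,Reject,FALSE,TRUE,printed stigma verdict conflicts with both parents belonging to G1
Cayanne,Picholine,Reject,Accept,TRUE,FALSE,
Cayanne,Arbequina,Reject,Accept,TRUE,FALSE,
Clermontaise,Picholine,Reject,Accept,TRUE,FALSE,
Clermontaise,Arbequina,Reject,Accept,TRUE,FALSE,
Cayon,Picholine,Reject,Accept,TRUE,TRUE,printed ovary verdict conflicts with the stated R1R4 pair of the host (shared R1)
Cayon,Arbequina,Reject,Accept,TRUE,TRUE,printed ovary verdict conflicts with the stated R1R4 pair of the host (shared R1)
Picholine,Amellau,Accept,Reject,TRUE,FALSE,
Picholine,Picual,Accept,Reject,TRUE,FALSE,
Arbequina,Amellau,Accept,Reject,TRUE,FALSE,
Arbequina,Picual,Accept,Reject,TRUE,FALSE,
Frantoio,CayetRoux,Accept,Reject,TRUE,FALSE,
PetitRibier,CayetRoux,Accept,Reject,TRUE,FALSE,
Redouneil,Frantoio,Reject,Reject,FALSE,FALSE,
Redouneil,PetitRibier,Reject,Reject,FALSE,FALSE,
Salonenque,Frantoio,Reject,Reject,FALSE,FALSE,
Salonenque,PetitRibier,Reject,Reject,FALSE,FALSE,
Redouneil,Amellau,Reject,Reject,FALSE,TRUE,father listed with the G1 group although deciphered as G2 elsewhere
Salonenque,Amellau,Reject,Reject,FALSE,TRUE,father listed with the G1 group although deciphered as G2 elsewhere
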