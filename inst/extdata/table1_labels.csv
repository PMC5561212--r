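name,fda_label,chemical_class
Acetaminophen,B,Derivative of acetanilide
Acyclovir,B,"Nucleoside analog, DNA polymerase inhibitor"
Amoxicillin,B,Penicillin
Ascorbic acid,A,Vitamin C
Caffeine,C,"Methylxanthine, adenosine receptor antagonist, phosphodiesterase inhibitor"
Diphenhydramine,B,Ethanolamine-based Histamine-1 antihistamine
Doxylamine,A,Ethanolamine-based Histamine-1 antihistamine
Esomeprazole,B,Proton pump inhibitor
Folic acid,A,Vitamin B9
Isoniazid,C,Synthetic derivative of nicotinic acid
Loratadine,B,Piperidine Histamine H1 receptor antagonist
Metoclopramide,B,Dopamine D2 antagonist
Methyldopa,B,Adrenergic alpha2-agonist
Sitagliptin,B,Dipeptidyl peptidase 4 inhibitor
Thiamine,A,Vitamin B1
5-Fluorouracil,D,Nucleoside metabolic inhibitor
Bosentan,X,Endothelin receptor antagonist
Busulfan,D,Alkylating agent
Carbamazepine,D,Tricyclic compound related to tricyclic antidepressants
Diethylstilbestrol,X,Non-steroidal oestrogen hormone
Diphenylhydantoin,D,Hydantoin derivative
Doxorubicin,D,Anthracycline topoisomerase inhibitor
Furosemide,C,Sulfamoylanthranilic acid derivative
Gefitinib,D,"Tyrosine kinase inhibitor, EGFR inhibitor"
Imatinib,D,"Tyrosine kinase inhibitor (Bcr-Abl, PDGFR, SCF/c-kit)"
Lovastatin,X,HMG-CoA reductase inhibitor
Methimazole,D,Thyroid hormone synthesis inhibitor
Sunitinib,D,"Tyrosine kinase inhibitor (VEGFR2, PDGFRb, c-kit, FLT3)"
Vandetanib,D,"Tyrosine kinase inhibitor (VEGFR2, EGFR)"
Ziprasidone,C,Benzothiazolylpiperazine derivative
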