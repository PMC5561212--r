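name,class,ic25_ahdf,ic25_h9,cmax,ldc
Acetaminophen,NON,401,71,24,160
Acyclovir,NON,285,267,5.65,60
Amoxicillin,NON,>1000,>1000,14.4,150
Ascorbic acid,NON,63,105,15,680
Caffeine,NON,129,85.4,10,130
Diphenhydramine,NON,31.4,2.4,0.06,2.4
Doxylamine,NON,45,87,0.12,45
Esomeprazole,NON,42.1,38.9,1.62,45
Folic acid,NON,894,888,0.27,900
Isoniazid,NON,488,370,3.09,500
Loratadine,NON,3.2,24,0.04,4
Metoclopramide,NON,154,162,0.04,120
Methyldopa,NON,15.9,23.2,7.5,25
Sitagliptin,NON,77.1,359,0.39,>360
Thiamine,NON,>1000,>1000,0.11,1000
5-Fluorouracil,TER,0.16,0.154,8.4,0.025
Bosentan,TER,19.9,43.8,8.17,16
Busulfan,TER,19.2,0.5,1.22,0.2
Carbamazepine,TER,28,21,11,10
Diethylstilbestrol,TER,6.1,8.8,0.0056,5
Diphenylhydantoin,TER,140,56,20,50
Doxorubicin,TER,0.003,0.0002,0.37,0.00015
Furosemide,TER,30,362,400,30
Gefitinib,TER,1.66,4.6,0.93,0.9
Imatinib,TER,2.71,9.5,1.56,0.75
Lovastatin,TER,0.68,0.30,0.01,0.01
Methimazole,TER,>1000,252,0.3,1.5
Sunitinib,TER,0.18,0.89,0.03,0.15
Vandetanib,TER,1.1,0.3,0.4,0.3
Ziprasidone,TER,2.71,4.4,0.2,1.25
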