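population,region,ordering_rank
TundraNentsi,SIB,1
Chipewyan,NAM,2
Cree,NAM,3
Ojibwa,NAM,4
Mixtec,MEA,5
Mixe,MEA,6
Zapotec,MEA,7
Kaqchikel,MEA,8
Cabecar,MEA,9
Guaymi,MEA,10
Inga,SAA,11
Quechua,SAA,12
Aymara,SAA,13
Huilliche,SAA,14
Wayuu,SAL,15
Arhuaco,SAL,16
Kogi,SAL,17
Zenu,SAL,18
Embera,SAL,19
Waunana,SAL,20
TicunaArara,SAL,21
TicunaTarapaca,SAL,22
Guarani,SAL,23
Ache,SAL,24
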