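family	baltimore_group	nucleic_acid
Adenoviridae	Group I	dsDNA
Herpesviridae	Group I	dsDNA
Poxviridae	Group I	dsDNA
Papillomaviridae	Group I	dsDNA
Polyomaviridae	Group I	dsDNA
Myoviridae	Group I	dsDNA
Siphoviridae	Group I	dsDNA
Podoviridae	Group I	dsDNA
Ackermannviridae	Group I	dsDNA
Herelleviridae	Group I	dsDNA
Baculoviridae	Group I	dsDNA
Iridoviridae	Group I	dsDNA
Mimiviridae	Group I	dsDNA
Phycodnaviridae	Group I	dsDNA
Marseilleviridae	Group I	dsDNA
Asfarviridae	Group I	dsDNA
Tectiviridae	Group I	dsDNA
Corticoviridae	Group I	dsDNA
Microviridae	Group II	ssDNA
Circoviridae	Group II	ssDNA
Parvoviridae	Group II	ssDNA
Anelloviridae	Group II	ssDNA
Inoviridae	Group II	ssDNA
Geminiviridae	Group II	ssDNA
Nanoviridae	Group II	ssDNA
Smacoviridae	Group II	ssDNA
Genomoviridae	Group II	ssDNA
Sedoreoviridae	Group III	dsRNA
Spinareoviridae	Group III	dsRNA
Picobirnaviridae	Group III	dsRNA
Partitiviridae	Group III	dsRNA
Totiviridae	Group III	dsRNA
Cystoviridae	Group III	dsRNA
Birnaviridae	Group III	dsRNA
Chrysoviridae	Group III	dsRNA
Picornaviridae	Group IV	ssRNA(+)
Caliciviridae	Group IV	ssRNA(+)
Astroviridae	Group IV	ssRNA(+)
Coronaviridae	Group IV	ssRNA(+)
Flaviviridae	Group IV	ssRNA(+)
Togaviridae	Group IV	ssRNA(+)
Matonaviridae	Group IV	ssRNA(+)
Virgaviridae	Group IV	ssRNA(+)
Tombusviridae	Group IV	ssRNA(+)
Secoviridae	Group IV	ssRNA(+)
Potyviridae	Group IV	ssRNA(+)
Fiersviridae	Group IV	ssRNA(+)
Nodaviridae	Group IV	ssRNA(+)
Dicistroviridae	Group IV	ssRNA(+)
Iflaviridae	Group IV	ssRNA(+)
Hepeviridae	Group IV	ssRNA(+)
Arteriviridae	Group IV	ssRNA(+)
Orthomyxoviridae	Group V	ssRNA(-)
Paramyxoviridae	Group V	ssRNA(-)
Pneumoviridae	Group V	ssRNA(-)
Rhabdoviridae	Group V	ssRNA(-)
Filoviridae	Group V	ssRNA(-)
Bornaviridae	Group V	ssRNA(-)
Arenaviridae	Group V	ssRNA(-)
Hantaviridae	Group V	ssRNA(-)
Peribunyaviridae	Group V	ssRNA(-)
Nairoviridae	Group V	ssRNA(-)
Phenuiviridae	Group V	ssRNA(-)
Retroviridae	Group VI	ssRNA-RT
Metaviridae	Group VI	ssRNA-RT
Pseudoviridae	Group VI	ssRNA-RT
Hepadnaviridae	Group VII	dsDNA-RT
Caulimoviridae	Group VII	dsDNA-RT
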