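species	thompson_kg	godfrey_kg	jungers_kg
Archaeolemur edwardsi	20.0	24.5	26.5
Archaeolemur majori	13.2	13.9	18.2
Megaladapis edwardsi	65.0	75.4	85.1
Megaladapis grandidieri	56.1	63.0	74.3
Megaladapis madagascariensis	31.6	38.0	46.5
Mesopropithecus globiceps	7.0	9.4	11.3
Mesopropithecus pithecoides	9.1	9.7	NA
Mesopropithecus dolichobrachion	8.1	NA	13.7
Palaeopropithecus ingens	30.3	39.5	41.5
Palaeopropithecus maximus	30.3	52.6	45.8
Babakotia radofilai	11.8	16.2	20.7
Archaeoindris fontoynontii	127.7	197.5	161.2
Pachylemur insignis	8.3	10.0	11.5
Pachylemur jullyi	9.8	12.8	13.4
Daubentonia robustus	9.8	13.5	14.2
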