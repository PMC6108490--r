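species,specimen,volume_mm3,structural_complexity_mm2,elastic_modulus_MPa,max_compressive_strength_N
Acinonyx jubatus,AMNH185436,161.75,398.83,320.44,784.40
Ailuropoda melanoleuca,AMNH89079,108.33,831.48,88.28,95.20
Ailurus fulgens,AMNH145071,161.75,407.57,277.74,394.80
Arctonyx collaris,AMNH57373,144.51,522.66,185.62,151.20
Bassariscus astutus,AMNH135964,106.11,372.58,119.87,80.40
Civettictis civetta,AMNH51818,149.81,511.89,203.33,214.00
Crocuta crocuta,AMNH187777,132.86,642.28,202.07,270.80
Cryptoprocta ferox,AMNH100463,133.65,620.35,108.31,96.40
Cynogale bennettii,AMNH173509,143.43,474.15,247.48,225.20
Eira barbara,AMNH32065,153.55,441.41,238.75,224.40
Enhydra lutris,AMNH24186,163.92,456.06,263.99,483.60
Erignathus barbatus,AMNH98,157.53,486.86,219.20,190.80
Eupleres goudotii,AMNH100484,125.41,372.58,133.57,104.80
Felis silvestris,AMNH81233,123.73,503.54,150.70,108.00
Fossa fossana,AMNH188210,179.72,269.42,335.58,714.40
Galidictis fasciata,AMNH100479,125.69,337.99,111.13,85.20
Genetta piscivora,AMNH51514,144.46,367.27,298.13,376.00
Gulo gulo,AMNH182936,179.85,309.42,344.09,940.80
Herpestes javanicus,AMNH101655,159.90,513.76,292.79,488.00
Hydrurga leptonyx,AMNH34920,124.78,952.08,117.24,164.40
Lontra canadensis,AMNH254476,176.93,375.71,311.53,641.20
Lycaon pictus,AMNHVP24218,114.62,742.53,117.83,108.40
Lynx rufus,AMNH24225,162.04,502.80,294.03,479.60
Mellivora capensis,AMNH89011,180.89,383.51,327.67,710.80
Mephitis mephitis,AMNH172133,123.49,437.59,119.78,86.40
Mirounga leonina,AMNH48161,152.12,701.74,249.75,618.80
Mungos mungo,AMNH185177,135.90,379.55,201.40,135.60
Mustela frenata,AMNH60508,138.70,283.45,195.02,209.20
Neofelis nebulosa,AMNH22919,161.13,516.18,266.98,381.60
Odobenus rosmarus,AMNH19270,140.34,714.23,49.91,32.00
Panthera pardus,AMNH113745,151.85,677.72,231.71,96.40
Paradoxurus hermaphroditus,AMNH163602,141.70,531.49,171.80,176.40
Phoca vitulina,AMNH100,138.22,608.71,145.38,181.20
Potos flavus,AMNH239990,173.53,319.41,328.67,693.20
Procyon lotor,AMNH24815,134.27,357.53,188.73,133.20
Spilogale putorius,AMNH35207,167.16,306.86,306.67,466.40
Taxidea taxus,AMNH120577,152.79,539.36,231.21,258.80
Ursus arctos,AMNH34408,172.16,519.90,276.61,533.20
Vulpes vulpes,AMNH88713,126.39,565.86,126.65,105.60
Zalophus californianus,AMNH63946,167.08,408.00,292.19,453.20
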