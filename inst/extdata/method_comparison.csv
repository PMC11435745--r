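pesticide,method,recovery_mean,recovery_sd
Acetamiprid,EN15662,87.9,4.6
Acetamiprid,AOAC,77.8,6.7
Acetamiprid,C18,75.9,0.6
Acetamiprid,PSA_C18,75.4,1.3
Azinphos-methyl,EN15662,84.0,1.8
Azinphos-methyl,AOAC,68.3,7.4
Azinphos-methyl,C18,75.4,4.8
Azinphos-methyl,PSA_C18,74.2,3.4
Azoxystrobin,EN15662,80.8,1.6
Azoxystrobin,AOAC,90.9,4.2
Azoxystrobin,C18,88.1,2.5
Azoxystrobin,PSA_C18,80.5,2.2
Carbendazim,EN15662,89.7,3.1
Carbendazim,AOAC,49.9,2.6
Carbendazim,C18,86.2,2.8
Carbendazim,PSA_C18,75.0,2.7
Carbofuran,EN15662,69.1,4.2
Carbofuran,AOAC,70.5,7.7
Carbofuran,C18,81.8,6.5
Carbofuran,PSA_C18,80.5,1.9
Clothianidin,EN15662,72.1,3.3
Clothianidin,AOAC,74.7,6.8
Clothianidin,C18,80.8,1.5
Clothianidin,PSA_C18,84.2,6.0
Dichlorvos,EN15662,63.5,6.4
Dichlorvos,AOAC,54.4,7.0
Dichlorvos,C18,77.2,3.0
Dichlorvos,PSA_C18,69.7,2.0
Dinotefuran,EN15662,72.7,1.9
Dinotefuran,AOAC,64.3,6.0
Dinotefuran,C18,77.9,3.8
Dinotefuran,PSA_C18,92.8,3.4
Diuron,EN15662,70.3,4.3
Diuron,AOAC,68.0,5.6
Diuron,C18,80.2,0.3
Diuron,PSA_C18,75.4,2.7
Flubendiamide,EN15662,89.3,4.8
Flubendiamide,AOAC,55.2,1.6
Flubendiamide,C18,80.2,2.5
Flubendiamide,PSA_C18,73.4,4.9
Hexaconazole,EN15662,70.4,5.1
Hexaconazole,AOAC,65.2,5.1
Hexaconazole,C18,81.9,1.7
Hexaconazole,PSA_C18,77.6,2.8
Pyrimisulfan,EN15662,86.5,4.0
Pyrimisulfan,AOAC,77.9,4.4
Pyrimisulfan,C18,83.6,4.6
Pyrimisulfan,PSA_C18,265.7,26.1
Terbuthylazine,EN15662,76.6,3.5
Terbuthylazine,AOAC,57.6,3.2
Terbuthylazine,C18,81.4,4.0
Terbuthylazine,PSA_C18,76.6,1.9
Thiacloprid,EN15662,81.9,5.9
Thiacloprid,AOAC,75.4,7.2
Thiacloprid,C18,80.3,3.7
Thiacloprid,PSA_C18,76.8,2.9
Thiamethoxam,EN15662,78.7,6.5
Thiamethoxam,AOAC,30.0,3.1
Thiamethoxam,C18,86.2,2.8
Thiamethoxam,PSA_C18,54.8,3.4
Tricyclazole,EN15662,78.4,3.2
Tricyclazole,AOAC,60.8,4.7
Tricyclazole,C18,85.4,3.7
Tricyclazole,PSA_C18,77.5,2.4
Azimsulfuron,EN15662,77.6,0.3
Azimsulfuron,AOAC,60.8,3.1
Azimsulfuron,C18,83.3,0.5
Azimsulfuron,PSA_C18,-3.5,4.9
Trifloxystrobin,EN15662,74.6,4.2
Trifloxystrobin,AOAC,59.5,1.5
Trifloxystrobin,C18,82.2,1.8
Trifloxystrobin,PSA_C18,80.6,1.9
Difenoconazole,EN15662,76.9,3.8
Difenoconazole,AOAC,48.4,5.0
Difenoconazole,C18,73.6,4.5
Difenoconazole,PSA_C18,79.5,2.0
Fenobucarb,EN15662,76.5,5.9
Fenobucarb,AOAC,74.6,2.8
Fenobucarb,C18,86.4,3.1
Fenobucarb,PSA_C18,80.7,3.4
Tebufenozide,EN15662,76.7,3.7
Tebufenozide,AOAC,90.4,3.4
Tebufenozide,C18,76.0,2.7
Tebufenozide,PSA_C18,76.6,0.5
Lufenuron,EN15662,96.7,5.0
Lufenuron,AOAC,74.5,3.9
Lufenuron,C18,77.5,5.6
Lufenuron,PSA_C18,80.0,3.6
Indoxacarb,EN15662,79.4,2.8
Indoxacarb,AOAC,67.8,3.6
Indoxacarb,C18,79.1,3.3
Indoxacarb,PSA_C18,98.4,3.2
Daimuron,EN15662,80.5,1.7
Daimuron,AOAC,36.5,2.2
Daimuron,C18,87.8,3.4
Daimuron,PSA_C18,80.7,1.3
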