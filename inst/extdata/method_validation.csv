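pesticide,matrix,r_squared,matrix_effect,lod,loq,recovery_loq,recovery_10loq,recovery_50loq,rsd_loq,rsd_10loq,rsd_50loq
Acetamiprid,Eel,0.9999,16.80,0.4,5,88.8,90.1,92.7,2.2,1.4,2.8
Acetamiprid,Flatfish,0.9993,-2.73,0.4,5,84.4,78.9,93.2,1.5,9.0,1.1
Acetamiprid,Abalone,1.0000,-5.60,0.25,3,88.9,90.1,87.9,2.8,1.1,2.9
Acetamiprid,Shrimp,0.9997,-9.55,0.6,7,90.8,92.8,93.7,1.5,1.4,2.1
Azinphos-methyl,Eel,0.9995,24.87,0.25,3,89.7,89.8,90.7,12.1,1.9,2.5
Azinphos-methyl,Flatfish,0.9990,5.85,0.25,3,84.0,86.6,93.1,6.1,3.1,4.6
Azinphos-methyl,Abalone,0.9989,-1.87,0.3,4,85.1,91.7,90.5,7.3,2.5,5.0
Azinphos-methyl,Shrimp,0.9998,0.77,0.4,5,95.4,90.0,92.7,4.1,2.3,1.0
Azoxystrobin,Eel,0.9998,19.44,0.3,4,89.4,90.5,92.1,2.2,1.1,4.1
Azoxystrobin,Flatfish,0.9994,-0.002,0.25,3,83.9,87.9,94.6,5.7,1.4,2.1
Azoxystrobin,Abalone,0.9998,-4.59,0.25,3,90.4,91.4,91.4,7.1,3.3,2.9
Azoxystrobin,Shrimp,0.9995,-5.99,0.3,4,85.8,93.8,94.0,5.7,1.5,3.3
Carbendazim,Eel,0.9995,15.06,0.3,4,86.7,85.8,88.6,4.5,3.4,4.9
Carbendazim,Flatfish,0.9989,-8.80,0.6,7,80.2,79.0,87.7,4.1,3.5,2.1
Carbendazim,Abalone,0.9999,-11.90,0.4,5,86.7,88.3,85.7,3.9,1.9,4.7
Carbendazim,Shrimp,0.9992,-15.11,0.25,3,87.6,91.0,89.1,8.4,3.3,5.2
Carbofuran,Eel,0.9996,24.36,0.25,3,91.8,88.8,92.7,4.7,1.2,3.8
Carbofuran,Flatfish,0.9994,0.83,0.25,3,87.2,87.9,93.7,4.2,1.4,1.4
Carbofuran,Abalone,0.9998,-0.31,0.3,4,93.4,89.5,88.4,5.0,0.7,2.9
Carbofuran,Shrimp,0.9995,-4.04,0.4,5,90.0,92.3,94.1,5.2,2.1,2.2
Clothianidin,Eel,0.9994,23.75,0.25,3,95.4,91.0,93.9,5.1,4.2,4.0
Clothianidin,Flatfish,0.9992,-2.45,0.3,4,75.2,83.4,91.0,11.2,1.9,2.9
Clothianidin,Abalone,0.9997,-6.90,0.3,4,85.8,88.6,85.9,10.5,3.7,2.4
Clothianidin,Shrimp,0.9983,-6.53,0.4,5,84.2,92.5,91.5,2.8,2.7,2.0
Dichlorvos,Eel,0.9996,15.87,0.4,5,84.0,88.1,92.7,7.1,2.1,1.7
Dichlorvos,Flatfish,0.9988,-4.16,0.4,5,82.7,85.1,93.7,8.5,1.5,3.2
Dichlorvos,Abalone,0.9999,-6.48,0.8,10,88.9,90.8,91.4,5.6,2.4,2.7
Dichlorvos,Shrimp,0.9993,-9.03,0.8,10,71.7,89.7,92.6,9.9,1.6,2.3
Dinotefuran,Eel,0.9998,5.45,0.3,4,87.1,88.9,91.4,5.3,1.6,1.6
Dinotefuran,Flatfish,0.9990,-1.80,0.3,4,82.1,84.8,90.2,3.9,2.5,1.6
Dinotefuran,Abalone,0.9999,-9.93,0.4,5,89.2,88.7,87.1,6.5,1.3,3.0
Dinotefuran,Shrimp,0.9996,25.45,0.4,5,88.1,89.5,91.9,1.6,2.7,2.0
Diuron,Eel,0.9996,27.79,0.4,5,91.5,89.0,92.0,4.3,1.6,1.6
Diuron,Flatfish,0.9991,-1.96,0.25,3,84.8,83.5,92.0,5.7,1.8,0.5
Diuron,Abalone,0.9999,-3.49,0.3,4,93.2,89.3,89.6,3.6,1.9,2.1
Diuron,Shrimp,0.9991,-3.49,0.3,4,93.2,89.3,89.6,3.6,1.9,2.1
Flubendiamide,Eel,0.9991,21.29,0.25,3,88.3,87.3,88.5,6.2,2.7,5.9
Flubendiamide,Flatfish,0.9976,7.12,0.4,4,92.8,88.8,95.1,5.6,3.1,3.8
Flubendiamide,Abalone,0.9995,2.04,0.4,4,86.2,93.4,90.7,8.1,1.5,4.3
Flubendiamide,Shrimp,0.9965,0.89,0.25,3,95.3,92.8,93.7,10.7,4.1,4.9
Hexaconazole,Eel,0.9921,-1.77,0.25,3,88.3,93.9,97.1,4.9,1.2,3.8
Hexaconazole,Flatfish,0.9988,-2.58,0.25,3,83.7,84.9,89.3,5.8,3.2,2.9
Hexaconazole,Abalone,0.9996,-8.25,0.25,3,77.6,90.5,87.9,13.2,2.3,3.1
Hexaconazole,Shrimp,0.9990,-7.47,0.25,3,82.9,91.4,92.9,5.8,2.9,5.2
Pyrimisulfan,Eel,0.9998,13.62,0.4,5,90.3,89.0,92.2,1.9,1.2,3.8
Pyrimisulfan,Flatfish,0.9990,6.35,0.3,4,87.6,86.6,93.4,2.0,1.2,1.1
Pyrimisulfan,Abalone,0.9996,1.08,0.25,3,90.2,90.2,89.2,2.7,1.1,2.5
Pyrimisulfan,Shrimp,0.9997,3.16,0.3,4,88.6,90.9,92.8,1.2,1.8,2.1
Terbuthylazine,Eel,0.9995,28.46,0.4,5,88.8,86.7,90.1,2.6,0.6,3.7
Terbuthylazine,Flatfish,0.9994,-1.35,0.25,3,87.0,85.7,90.9,5.1,1.8,1.5
Terbuthylazine,Abalone,0.9999,-5.93,0.3,4,90.1,91.6,89.7,4.4,1.3,2.9
Terbuthylazine,Shrimp,0.9994,-4.81,0.3,4,82.4,92.1,91.5,6.2,3.5,3.8
Thiacloprid,Eel,0.9999,20.48,0.4,5,84.8,90.3,91.9,2.8,1.2,4.2
Thiacloprid,Flatfish,0.9995,0.82,0.4,5,85.0,86.0,92.5,2.3,1.9,1.1
Thiacloprid,Abalone,0.9939,-2.12,0.3,4,88.4,89.9,86.7,2.8,1.7,0.4
Thiacloprid,Shrimp,0.9994,-6.37,0.6,7,86.1,93.0,93.0,2.4,1.3,1.4
Thiamethoxam,Eel,0.9997,16.73,0.25,3,93.4,90.2,93.9,7.7,1.1,2.7
Thiamethoxam,Flatfish,0.9995,-11.66,0.6,7,81.2,82.5,91.9,2.8,2.6,1.8
Thiamethoxam,Abalone,1.0000,-14.10,0.3,4,90.6,89.0,87.5,5.1,1.1,2.3
Thiamethoxam,Shrimp,0.9991,-6.82,0.4,5,85.0,92.1,94.2,4.5,2.3,2.4
Tricyclazole,Eel,0.9997,-0.08,0.25,3,90.1,90.7,101.3,3.3,0.8,2.4
Tricyclazole,Flatfish,0.9993,-20.33,0.4,5,86.3,87.3,106.3,1.0,2.0,1.9
Tricyclazole,Abalone,0.9998,-19.23,0.4,5,85.6,88.9,93.9,5.1,0.8,2.2
Tricyclazole,Shrimp,0.9979,-26.81,0.3,4,90.6,95.4,101.0,3.6,1.1,1.7
Azimsulfuron,Eel,0.9998,15.92,0.3,4,87.5,88.2,91.1,3.1,1.5,2.2
Azimsulfuron,Flatfish,0.9993,6.15,0.3,4,83.0,83.4,90.5,3.6,1.7,1.9
Azimsulfuron,Abalone,0.9997,1.80,0.3,4,85.8,90.0,89.2,3.7,2.1,2.1
Azimsulfuron,Shrimp,0.9997,4.49,0.25,3,85.1,88.2,90.9,3.8,1.7,2.8
Trifloxystrobin,Eel,0.9990,27.81,0.4,5,96.8,90.9,92.7,4.5,3.0,3.8
Trifloxystrobin,Flatfish,0.9984,-3.56,0.25,3,90.4,90.5,95.8,2.7,2.3,1.8
Trifloxystrobin,Abalone,0.9998,-3.16,0.25,3,87.8,90.5,88.7,4.3,2.1,2.1
Trifloxystrobin,Shrimp,0.9986,-10.76,0.25,3,87.1,94.6,100.5,7.8,2.1,1.5
Difenoconazole,Eel,0.9993,16.22,0.3,4,86.3,88.7,92.5,1.8,1.4,2.2
Difenoconazole,Flatfish,0.9990,1.25,0.3,4,83.0,86.1,91.9,3.4,0.7,1.0
Difenoconazole,Abalone,1.0000,-5.08,0.25,3,87.6,91.8,90.5,5.8,0.8,2.5
Difenoconazole,Shrimp,0.9996,-4.78,0.25,3,86.3,92.3,91.7,4.8,1.5,2.4
Fenobucarb,Eel,0.9997,18.71,0.3,4,87.6,88.9,92.2,3.9,1.8,2.2
Fenobucarb,Flatfish,0.9990,-0.45,0.3,4,81.7,86.0,91.7,7.4,1.2,2.3
Fenobucarb,Abalone,0.9997,-4.37,0.3,4,88.7,92.2,89.1,5.3,1.8,2.9
Fenobucarb,Shrimp,0.9994,-2.13,0.25,3,90.1,93.7,93.1,3.1,1.7,2.0
Tebufenozide,Eel,0.9998,22.51,0.25,3,92.1,90.6,93.9,2.8,1.8,3.9
Tebufenozide,Flatfish,0.9993,0.71,0.4,5,83.1,86.8,94.4,3.6,1.7,1.6
Tebufenozide,Abalone,0.9998,-3.82,0.3,4,84.2,91.5,89.0,4.6,1.7,1.9
Tebufenozide,Shrimp,0.9989,-3.61,0.4,5,90.5,91.6,93.8,3.7,2.1,4.3
Lufenuron,Eel,0.9993,20.25,0.4,5,87.6,86.6,87.2,5.3,2.4,6.7
Lufenuron,Flatfish,0.9997,-10.19,0.4,5,78.8,91.9,91.6,12.0,7.0,3.1
Lufenuron,Abalone,0.9997,-17.85,0.3,4,80.4,91.9,84.1,14.2,2.2,6.9
Lufenuron,Shrimp,0.9992,-3.16,0.25,3,93.7,94.0,95.0,12.9,2.5,4.9
Indoxacarb,Eel,0.9997,15.40,0.4,5,90.8,89.2,92.6,2.2,2.4,5.1
Indoxacarb,Flatfish,0.9976,5.46,0.3,4,81.6,88.7,93.7,12.5,2.6,2.7
Indoxacarb,Abalone,0.9997,-1.23,0.4,5,94.1,90.9,90.5,7.7,2.0,1.2
Indoxacarb,Shrimp,0.9988,-2.55,0.3,4,89.2,90.8,92.8,7.2,2.3,6.6
Daimuron,Eel,0.9998,16.93,0.3,4,87.2,88.9,91.4,1.3,1.5,3.6
Daimuron,Flatfish,0.9993,1.61,0.3,4,87.2,86.7,93.1,1.7,0.8,0.9
Daimuron,Abalone,0.9999,-2.36,0.25,3,88.7,91.4,90.4,1.6,0.9,2.3
Daimuron,Shrimp,0.9997,-3.47,0.25,3,89.1,91.6,93.3,3.0,1.6,2.7
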