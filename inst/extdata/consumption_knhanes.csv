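species,mean_intake,extreme_intake,imputed
Abalone,0.6000,13.8000,FALSE
Carp,0.4800,12.1200,TRUE
Chinese muddy loach,0.9600,43.6800,FALSE
Crucian carp,0.4800,12.1200,TRUE
Eel,1.3200,24.2400,FALSE
Far eastern catfish,0.4800,12.1200,TRUE
Flathead mullet,0.4800,12.1200,TRUE
Korean rockfish,1.2000,31.2000,FALSE
Mirror carp,0.4800,12.1200,TRUE
Olive flounder,1.3500,48.4500,FALSE
Rainbow trout,0.4800,12.1200,TRUE
Red seabream,0.4800,12.1200,TRUE
Sea bass,0.4800,12.1200,TRUE
Starry flounder,0.4800,12.1200,TRUE
Whiteleg shrimp,1.8000,50.4000,FALSE
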