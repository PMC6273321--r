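formula,name,n_lipo_alkaloids,first_detected
C3H6O2,Propanoic acid,,FALSE
C4H4O4,Fumaric acid,2,FALSE
C4H6O2,Butenoic acid,1,TRUE
C4H6O3,Hydroxybutenoic acid,1,TRUE
C4H6O4,Succinic acid,2,FALSE
C4H6O5,Malic acid,,FALSE
C4H8O2,Butanoic acid,3,FALSE
C4H8O3,Hydroxybutanoic acid,3,FALSE
C4H8O4,Dihydroxybutanoic acid,1,TRUE
C5H6O4,Glutaconic acid,2,FALSE
C5H6O5,Oxoglutaric acid,1,TRUE
C5H8O4,Glutaric acid,1,FALSE
C5H10O2,Valeric acid,4,FALSE
C5H10O3,Hydroxyvaleric acid,1,TRUE
C6H6O6,Aconitic acid,5,TRUE
C6H10O4,Adipic acid,3,FALSE
C6H10O5,Hydroxyadipic acid,5,TRUE
C6H12O2,Hexanoic acid,1,FALSE
C7H8O4,Heptadienedioic acid,1,TRUE
C7H8O6,Dioxoheptanedioic acid,1,TRUE
C7H12O4,Pimelic acid,,FALSE
C8H14O4,Suberic acid,,FALSE
C8H16O2,Octanoic acid,1,TRUE
C9H16O3,Hydroxynonenoic acid,3,TRUE
C9H16O4,Azelaic acid,2,FALSE
C9H18O2,Nonanoic acid,1,TRUE
C10H18O4,Sebacic acid,1,FALSE
C11H20O4,Undecanedioic acid,,FALSE
C11H22O4,Dihydroxyundecanoic acid,2,TRUE
C12H20O4,Dodecenedioic acid,1,TRUE
C12H24O2,Lauric acid,1,FALSE
C14H24O2,Tetradecadienoic acid,,FALSE
C14H26O2,Tetradecenoic acid,,FALSE
C14H28O2,Myristic acid,1,FALSE
C15H28O2,Pentadecenoic acid,2,FALSE
C15H30O2,Pentadecanoic acid,4,FALSE
C16H28O2,Palmitadienoic acid,1,FALSE
C16H30O2,Palmitoleic acid,4,FALSE
C16H32O2,Palmitic acid,11,FALSE
C17H30O2,Heptadecadienoic acid,2,TRUE
C17H32O2,Heptadecenoic acid,1,FALSE
C17H34O2,Heptadecanoic acid,2,FALSE
C18H30O2,Linolenic acid,9,FALSE
C18H30O3,Hydroxyoctadecatrienoic acid,4,TRUE
C18H32O2,Linoleic acid,12,FALSE
C18H32O3,Hydroxyoctadecadienoic acid,5,TRUE
C18H32O4,Dihydroxyoctadecadienoic acid,3,TRUE
C18H34O2,Oleic acid,11,FALSE
C18H34O3,Hydroxyoctadecenoic acid,4,TRUE
C18H34O4,Dihydroxyoctadecenoic acid,4,TRUE
C18H34O5,Trihydroxyoctadecenoic acid,4,TRUE
C18H36O2,Stearic acid,3,FALSE
C18H36O3,Hydroxystearic acid,1,TRUE
C18H36O4,Dihydroxy stearic acid,2,TRUE
C19H32O2,Nonadecatrienoic acid,,FALSE
C19H34O2,Nonadecadienoic acid,,FALSE
C19H36O2,Nonadecenoic acid,,FALSE
C19H36O5,Trihydroxynonadecenoic acid,1,TRUE
C19H38O2,Nonadecanoic acid,,FALSE
C20H30O2,Eicosapentaenoic acid,,FALSE
C20H32O2,Eicosatetraenoic acid,,FALSE
C20H34O2,Eicosatrienoic acid,,FALSE
C20H34O4,Dihydroxyeicosatrienoic acid,1,TRUE
C20H36O2,Eicosadienoic acid,1,FALSE
C20H38O2,Eicosenoic acid,,FALSE
C20H40O2,Eicosanoic acid,,FALSE
C21H32O2,Henicosapentaenoic acid,,FALSE
C21H34O2,Henicosatetraenoic acid,,FALSE
C21H34O4,Dihydroxyhenicosatetrenoic acid,1,TRUE
C22H32O2,Docosahexaenoic acid,,FALSE
C22H44O2,Docosanoic acid,3,FALSE
C23H42O2,Tricosadienoic Acid,,FALSE
C23H44O2,Tricosenoic Acid,,FALSE
C23H46O2,Tricosanoic Acid,1,TRUE
C24H46O2,Tetracosenoic acid,,FALSE
C24H48O2,Tetrecosanoic acid,2,FALSE
C25H50O2,Pentacosanoic acid,,FALSE
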