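abbreviation,name,formula
fmr,fumaric acid,C4H4O4
bte,butenoic acid,C4H6O2
hbte,hydroxybutenoic acid,C4H6O3
scn,succinic acid,C4H6O4
btn,butanoic acid,C4H8O2
hbtn,hydroxybutanoic acid,C4H8O3
dhbtn,dihydroxybutanoic acid,C4H8O4
gtn,glutaconic acid,C5H6O4
ogtr,oxoglutaric acid,C5H6O5
gtr,glutaric acid,C5H8O4
vlr,valeric acid,C5H10O2
hvlr,hydroxyvaleric acid,C5H10O3
act,aconitic acid,C6H6O6
adp,adipic acid,C6H10O4
hadp,hydroxyadipic acid,C6H10O5
hxn,hexanoic acid,C6H12O2
dohpnd,dioxoheptanedioic acid,C7H8O6
otn,octanoic acid,C8H16O2
hnne,hydroxynonenoic acid,C9H16O3
azl,azelaic acid,C9H16O4
nnn,nonanoic acid,C9H18O2
sbc,sebacic acid,C10H18O4
dhudn,dihydroxyundecanoic acid,C11H22O4
dded,dodecenedioic acid,C12H20O4
laur,lauric acid,C12H24O2
myr,myristic acid,C14H28O2
ptde,pentadecenoic acid,C15H28O2
ptdn,pentadecanoic acid,C15H30O2
pmde,palmitadienoic acid,C16H28O2
pme,palmitoleic acid,C16H30O2
pal,palmitic acid,C16H32O2
hpdde,heptadecadienoic acid,C17H30O2
hpde,heptadecenoic acid,C17H32O2
hpdn,heptadecanoic acid,C17H34O2
linolen,linolenic acid,C18H30O2
hodt,hydroxyoctadecatrienoic acid,C18H30O3
lino,linoleic acid,C18H32O2
hodd,hydroxyoctadecadienoic acid,C18H32O3
dhodd,dihydroxyoctadecadienoic acid,C18H32O4
ole,oleic acid,C18H34O2
hode,hydroxyoctadecenoic acid,C18H34O3
dhode,dihydroxyoctadecenoic acid,C18H34O4
thode,trihydroxyoctadecenoic acid,C18H34O5
str,stearic acid,C18H36O2
hstr,hydroxystearic acid,C18H36O3
dhstr,dihydroxystearic acid,C18H36O4
thnde,trihydroxynonadecenoic acid,C19H36O5
dhecte,dihydroxyeicosatrienoic acid,C20H34O4
ecde,eicosadienoic acid,C20H36O2
dhhctte,dihydroxyhenicosatetraenoic acid,C21H34O4
dcn,docosanoic acid,C22H44O2
tcn,tricosanoic acid,C23H46O2
ttcn,tetracosanoic acid,C24H48O2
gvl,glucovanillic acid,C14H18O9
gcf,glucocaffeic acid,C15H18O9
gfr,glucoferulic acid,C16H20O9
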