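name,formula,n_ome,has_3_oh,has_13_oh_14_obz,has_15_oh_16_ome,has_3_oac,n_substituent,absent_losses,aliases
3-Ac-BMA,C33H45NO11,4,FALSE,TRUE,TRUE,TRUE,Me,FA+3CH3OH;FA+2CH3OH+BzOH,
10-OH-BA,C32H45NO11,4,TRUE,TRUE,TRUE,FALSE,Et,,
10-OH-BMA,C31H43NO11,4,TRUE,TRUE,TRUE,FALSE,Me,,
BA,C32H45NO10,4,TRUE,TRUE,TRUE,FALSE,Et,,
BMA,C31H43NO10,4,TRUE,TRUE,TRUE,FALSE,Me,,
DBA,C32H45NO9,4,FALSE,TRUE,TRUE,FALSE,Et,FA+3CH3OH,3-DBA
BHA,C31H43NO9,4,FALSE,TRUE,TRUE,FALSE,Me,,
"3,13-DDBA",C32H45NO8,4,FALSE,FALSE,TRUE,FALSE,Et,,
3-DMDBA,C31H43NO8,3,FALSE,TRUE,TRUE,FALSE,Et,,DMDBA
13-DMDBA,C31H43NO8,3,TRUE,FALSE,TRUE,FALSE,Et,,
DMBHA,C30H41NO8,3,FALSE,TRUE,TRUE,FALSE,Me,FA+CH3OH+CO,
"3,13-DMDDBA",C31H43NO7,3,FALSE,FALSE,TRUE,FALSE,Et,,DMDDBA
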