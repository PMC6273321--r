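skeleton,losses,printed_mz,weak,misprint
3-Ac-BMA,FA,614.2965,FALSE,FALSE
3-Ac-BMA,FA+CH3OH,582.2703,FALSE,FALSE
3-Ac-BMA,FA+CH3OH+CO,554.2754,FALSE,FALSE
3-Ac-BMA,FA+2CH3OH,550.2441,FALSE,FALSE
3-Ac-BMA,FA+2CH3OH+CO,522.2492,FALSE,FALSE
3-Ac-BMA,FA+3CH3OH+BzOH,396.1811,FALSE,FALSE
3-Ac-BMA,FA+3CH3OH+BzOH+AcOH,336.1600,FALSE,FALSE
10-OH-BA,FA,602.2965,FALSE,FALSE
10-OH-BA,FA+CH3OH,570.2703,FALSE,FALSE
10-OH-BA,FA+CH3OH+H2O,552.2597,FALSE,FALSE
10-OH-BA,FA+CH3OH+CO,542.2754,FALSE,FALSE
10-OH-BA,FA+2CH3OH,538.2441,FALSE,FALSE
10-OH-BA,FA+2CH3OH+H2O,520.2335,FALSE,FALSE
10-OH-BA,FA+2CH3OH+CO,510.2492,FALSE,FALSE
10-OH-BA,FA+3CH3OH,506.2179,FALSE,FALSE
10-OH-BA,FA+2CH3OH+BzOH,,TRUE,FALSE
10-OH-BA,FA+3CH3OH+BzOH,384.1811,FALSE,FALSE
10-OH-BMA,FA,588.2809,FALSE,FALSE
10-OH-BMA,FA+CH3OH,556.2547,FALSE,FALSE
10-OH-BMA,FA+CH3OH+H2O,538.2441,FALSE,FALSE
10-OH-BMA,FA+CH3OH+CO,528.2597,FALSE,FALSE
10-OH-BMA,FA+2CH3OH,524.2284,FALSE,FALSE
10-OH-BMA,FA+2CH3OH+H2O,506.2179,FALSE,FALSE
10-OH-BMA,FA+2CH3OH+CO,496.2335,FALSE,FALSE
10-OH-BMA,FA+3CH3OH,492.2022,FALSE,FALSE
10-OH-BMA,FA+2CH3OH+BzOH,,TRUE,FALSE
10-OH-BMA,FA+3CH3OH+BzOH,370.1654,FALSE,FALSE
BA,FA,586.3016,FALSE,FALSE
BA,FA+CH3OH,554.2754,FALSE,FALSE
BA,FA+CH3OH+H2O,536.2648,FALSE,FALSE
BA,FA+CH3OH+CO,526.2805,FALSE,FALSE
BA,FA+2CH3OH,522.2492,FALSE,FALSE
BA,FA+2CH3OH+H2O,504.2386,FALSE,FALSE
BA,FA+2CH3OH+CO,494.2543,FALSE,FALSE
BA,FA+3CH3OH,490.2230,FALSE,FALSE
BA,FA+2CH3OH+BzOH,,TRUE,FALSE
BA,FA+3CH3OH+BzOH,368.1862,FALSE,FALSE
BMA,FA,572.2860,FALSE,FALSE
BMA,FA+CH3OH,540.2597,FALSE,FALSE
BMA,FA+CH3OH+H2O,522.2492,FALSE,FALSE
BMA,FA+CH3OH+CO,512.2648,FALSE,FALSE
BMA,FA+2CH3OH,508.2335,FALSE,FALSE
BMA,FA+2CH3OH+H2O,490.2230,FALSE,FALSE
BMA,FA+2CH3OH+CO,480.2386,FALSE,FALSE
BMA,FA+3CH3OH,476.2073,FALSE,FALSE
BMA,FA+2CH3OH+BzOH,,TRUE,FALSE
BMA,FA+3CH3OH+BzOH,354.1705,FALSE,FALSE
DBA,FA,570.3067,FALSE,FALSE
DBA,FA+CH3OH,538.2805,FALSE,FALSE
DBA,FA+CH3OH+CO,510.2856,FALSE,FALSE
DBA,FA+2CH3OH,506.2543,FALSE,FALSE
DBA,FA+2CH3OH+CO,478.2593,FALSE,FALSE
DBA,FA+2CH3OH+BzOH,,TRUE,FALSE
DBA,FA+3CH3OH+BzOH,352.1913,FALSE,FALSE
BHA,FA,556.2910,FALSE,FALSE
BHA,FA+CH3OH,524.2648,FALSE,FALSE
BHA,FA+CH3OH+CO,496.2704,FALSE,FALSE
BHA,FA+2CH3OH,492.2386,FALSE,FALSE
BHA,FA+2CH3OH+CO,464.2437,FALSE,FALSE
BHA,FA+3CH3OH,460.2124,FALSE,FALSE
BHA,FA+2CH3OH+BzOH,,TRUE,FALSE
BHA,FA+3CH3OH+BzOH,338.1756,FALSE,FALSE
"3,13-DDBA",FA,554.3118,FALSE,FALSE
"3,13-DDBA",FA+CH3OH,522.2856,FALSE,FALSE
"3,13-DDBA",FA+CH3OH+CO,494.2906,FALSE,FALSE
"3,13-DDBA",FA+2CH3OH,490.2593,FALSE,FALSE
"3,13-DDBA",FA+2CH3OH+CO,462.2644,FALSE,FALSE
"3,13-DDBA",FA+3CH3OH,458.2331,FALSE,FALSE
3-DMDBA,FA,540.2961,FALSE,FALSE
3-DMDBA,FA+CH3OH,508.2699,FALSE,FALSE
3-DMDBA,FA+CH3OH+CO,480.2750,FALSE,FALSE
3-DMDBA,FA+2CH3OH,476.2437,FALSE,FALSE
3-DMDBA,FA+2CH3OH+CO,448.2448,FALSE,TRUE
3-DMDBA,FA+2CH3OH+BzOH,354.2069,FALSE,FALSE
13-DMDBA,FA,540.2961,FALSE,FALSE
13-DMDBA,FA+CH3OH,508.2699,FALSE,FALSE
13-DMDBA,FA+CH3OH+H2O,490.2593,FALSE,FALSE
13-DMDBA,FA+CH3OH+CO,480.2750,FALSE,FALSE
13-DMDBA,FA+2CH3OH,476.2437,FALSE,FALSE
13-DMDBA,FA+2CH3OH+H2O,458.2331,FALSE,FALSE
13-DMDBA,FA+2CH3OH+CO,448.2448,FALSE,TRUE
DMBHA,FA,526.2805,FALSE,FALSE
DMBHA,FA+CH3OH,494.2543,FALSE,FALSE
DMBHA,FA+2CH3OH,462.2280,FALSE,FALSE
DMBHA,FA+2CH3OH+CO,434.2331,FALSE,FALSE
DMBHA,FA+2CH3OH+BzOH,340.1913,FALSE,FALSE
"3,13-DMDDBA",FA,524.3014,FALSE,TRUE
"3,13-DMDDBA",FA+CH3OH,492.2750,FALSE,FALSE
"3,13-DMDDBA",FA+CH3OH+CO,464.2801,FALSE,FALSE
"3,13-DMDDBA",FA+2CH3OH,460.2488,FALSE,FALSE
"3,13-DMDDBA",FA+2CH3OH+CO,432.2539,FALSE,FALSE
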