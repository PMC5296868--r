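analyte,units,panel_source,mean_wt,sd_wt,n_wt,mean_het,sd_het,n_het,printed_p,lloq,status
EGF,pg/mL,inflammation,201,31.7,4,211,24.6,4,0.64,,quantified
Eotaxin,pg/mL,inflammation,2170,1044,4,1368,173,4,0.18,,quantified
IL-1 beta,ng/mL,inflammation,8.975,2.1,4,9.45,1.3,4,0.71,,quantified
IL-18,ng/mL,inflammation,20.8,4,4,25.3,1.5,4,0.08,,quantified
IP-10,pg/mL,inflammation,60,42.2,4,64.5,19.8,4,0.85,,quantified
LIF,pg/mL,inflammation,915.3,173.6,4,722.8,129.3,4,0.13,,quantified
MCP-1,pg/mL,inflammation,55.5,28.9,4,43,17.6,4,0.49,,quantified
MCP-3,pg/mL,inflammation,293.5,195.4,4,204.8,30.2,4,0.4,,quantified
MCP-5,pg/mL,inflammation,17.7,7.5,4,16.5,3.3,4,0.78,,quantified
M-CSF-1,ng/mL,inflammation,3.45,1.1,4,4.3,0.2,4,0.19,,quantified
MDC,pg/mL,inflammation,2157.5,1099.5,4,1470,216.9,4,0.27,,quantified
MIP-1 alpha,ng/mL,inflammation,5.4,0.8,4,5.4,0.5,4,1,,quantified
MIP-3 beta,ng/mL,inflammation,3.3,0.6,4,2.5,0.2,4,0.05,,quantified
Thrombopoietin,ng/mL,inflammation,35,7.7,4,37.5,5.2,4,0.61,,quantified
TIMP-1,ng/mL,inflammation,1.4,1,4,1.15,0.1,4,0.65,,quantified
VEGF-A,pg/mL,inflammation,185.5,28.4,4,192.5,27.8,4,0.74,,quantified
Glucose,mg/dl,chemistry,253.3,20.6,4,238.2,85.4,4,0.74,,quantified
BUN,mg/dl,chemistry,22.8,4.2,4,23,4.5,4,0.93,,quantified
Creatine,mg/dl,chemistry,0.05,0.05,4,0.02,0,4,0.4,,quantified
Phosphate,mg/dl,chemistry,6.45,0.1,4,7.68,1.1,4,0.06,,quantified
Total Protein,g/dl,chemistry,3.5,0.1,4,3.4,0.2,4,0.48,,quantified
Albumin,g/dl,chemistry,2,0.01,4,1.94,0.1,4,0.41,,quantified
Globulin,g/dl,chemistry,1.5,0.05,4,1.46,0.1,4,0.82,,quantified
Albumin/Globulin,ratio,chemistry,1.4,0.06,4,1.34,0.2,4,0.91,,quantified
Total Bilirubin,mg/dl,chemistry,0.1,0,4,0.18,0.2,4,0.41,,quantified
ALP,U/L,chemistry,0.75,0.5,4,0.8,0.4,4,0.88,,quantified
GGT,U/L,chemistry,1,0.8,4,1.2,0.4,4,0.65,,quantified
ALT,U/L,chemistry,33,11.4,4,40.4,24.4,4,0.6,,quantified
AST,U/L,chemistry,60,17.6,4,78.6,32.4,4,0.34,,quantified
Cholesterol,mg/dl,chemistry,54.5,11.2,4,56.2,15,4,0.86,,quantified
FGF-9,ng/mL,inflammation,,,,,,,,2.4,below_lloq
FGF-basic,ng/mL,inflammation,,,,,,,,9.6,below_lloq
GM-CSF,pg/mL,inflammation,,,,,,,,15,below_lloq
KC/GRO,ng/mL,inflammation,,,,,,,,0.028,below_lloq
IFN-gamma,pg/mL,inflammation,,,,,,,,182,below_lloq
IL-1 alpha,pg/mL,inflammation,,,,,,,,100,below_lloq
IL-2,pg/mL,inflammation,,,,,,,,70,below_lloq
IL-3,pg/mL,inflammation,,,,,,,,5.9,below_lloq
IL-4,pg/mL,inflammation,,,,,,,,60,below_lloq
IL-5,ng/mL,inflammation,,,,,,,,0.6,below_lloq
IL-6,pg/mL,inflammation,,,,,,,,4.7,below_lloq
IL-7,ng/mL,inflammation,,,,,,,,0.19,below_lloq
IL-10,pg/mL,inflammation,,,,,,,,125,below_lloq
IL-11,pg/mL,inflammation,,,,,,,,56,below_lloq
IL-12p70,ng/mL,inflammation,,,,,,,,0.091,below_lloq
IL-17A,ng/mL,inflammation,,,,,,,,0.018,below_lloq
MIP-1 beta,pg/mL,inflammation,,,,,,,,142,below_lloq
MIP-2,pg/mL,inflammation,,,,,,,,11,below_lloq
Oncostatin-M,ng/mL,inflammation,,,,,,,,0.24,below_lloq
SCF,pg/mL,inflammation,,,,,,,,652,below_lloq
TNF-alpha,ng/mL,inflammation,,,,,,,,0.082,below_lloq
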