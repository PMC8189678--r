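comp_id,parent,name
PSU,U,pseudouridine
H2U,U,5-6-dihydrouridine
5MU,U,5-methyluridine (ribothymidine)
4SU,U,4-thiouridine
OMU,U,2'-O-methyluridine
UR3,U,3-methyluridine
70U,U,5-carboxymethylaminomethyluridine
S4U,U,4-thiouridine (alt code)
5MC,C,5-methylcytidine
OMC,C,2'-O-methylcytidine
4OC,C,N4-2'-O-dimethylcytidine
M4C,C,N4-methylcytidine
1MA,A,1-methyladenosine
2MA,A,2-methyladenosine
6MA,A,N6-methyladenosine
MA6,A,N6-dimethyladenosine
OMA,A,2'-O-methyladenosine
A2M,A,2'-O-methyladenosine (alt code)
T6A,A,N6-threonylcarbamoyladenosine
1MG,G,1-methylguanosine
2MG,G,N2-methylguanosine
M2G,G,N2-dimethylguanosine
7MG,G,7-methylguanosine
OMG,G,2'-O-methylguanosine
G7M,G,7-methylguanosine (alt code)
YYG,G,wybutosine
YG,G,wyosine
QUO,G,queuosine
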