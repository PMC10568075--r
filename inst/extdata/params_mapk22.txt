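# synthetic mass-action parameterization of the MAPK 2+2 motif (reduced and full forms)
# units: dimensionless concentrations, arbitrary time
E1tot = 0.6
P1tot = 0.24
P2tot = 0.24
Ktot = 1.2
Atot = 1.2
a1 = 2.83333333333333
d1 = 0.333333333333333
k1 = 0.0166666666666667
a2 = 1.11
d2 = 0.333333333333333
k2 = 1
a3 = 0.666666666666667
d3 = 0.333333333333333
k3 = 0.266666666666667
a4 = 2.66666666666667
d4 = 0.333333333333333
k4 = 0.166666666666667
a5 = 212.5
d5 = 25
k5 = 0.5
a6 = 83.25
d6 = 25
k6 = 75
a7 = 550
d7 = 25
k7 = 4.25
a8 = 650
d8 = 25
k8 = 3
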