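# synthetic reconstruction of the embryonic cell-cycle oscillator parameterization
# units: concentrations nM, time min
k_synth = 1.5
r = 0.5
acdc25 = 0.16
bcdc25 = 0.8
ec50_cdc25 = 35
ncdc25 = 11
awee1 = 0.08
bwee1 = 0.4
ec50_wee1 = 30
nwee1 = 3.5
adeg = 0.0006
bdeg = 0.08
kplx_on = 1.5
kplx_off = 1.5
ec50_plx = 40
nplx = 8
kapc_on = 1.5
kapc_off = 0.15
ec50_apc = 0.25
napc = 4
extra = 0
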