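# Electron collision mass stopping power of a generic condensed organic
# medium (liquid-water proxy), MeV cm^2/g.  Values above 1 keV are
# approximate transcriptions of ICRU-37/ESTAR-class compilations; below
# 1 keV they follow dielectric-model calculations for liquid water
# (Emfietzoglou-type), rounded.  Used density-scaled for all condensed
# layers.  Log-log interpolation between rows.
energy_eV	stopping_MeV_cm2_g
20	35
30	70
50	130
100	215
150	235
200	230
300	210
500	175
700	150
1000	126
1500	97
2000	81
3000	61
5000	42.6
10000	22.6
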