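# Elemental photoelectric mass attenuation coefficients, cm^2/g.
# Anchor-point transcription (approximate, few-percent level) from
# standard photoabsorption compilations (NIST XCOM / FFAST, Henke et al.
# At. Data Nucl. Data Tables 54, 181 (1993)); log-log (power-law)
# interpolation between rows reconstructs intermediate energies.
# Absorption-edge discontinuities are represented by paired rows just
# below/above the edge (C K 284.2 eV, N K 409.9 eV, O K 543.1 eV,
# P K 2145.5 eV).  Valid range 100 eV - 10 keV.
element	energy_eV	mu_rho_cm2g
H	100	6900
H	1000	6.9
H	1500	2.1
H	2000	0.93
H	4000	0.11
H	10000	0.007
C	100	30000
C	284.1	1400
C	284.3	40000
C	1000	2200
C	1500	690
C	2000	295
C	4000	41
C	10000	2.3
N	100	40000
N	409.8	1100
N	410	33000
N	1000	3310
N	1500	1070
N	2000	462
N	4000	64
N	10000	3.7
O	100	50000
O	543	900
O	543.2	26000
O	1000	4570
O	1500	1540
O	2000	680
O	4000	96
O	10000	5.7
P	100	20000
P	200	24000
P	1000	6300
P	1500	2150
P	2000	990
P	2145.4	830
P	2145.6	7600
P	3000	3000
P	5000	750
P	10000	110
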