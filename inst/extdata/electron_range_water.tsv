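# CSDA range of electrons in liquid water (density 1 g/cm3).
# Columns: energy_mev  csda_range_um
# Provenance: condensed transcription of ESTAR-consistent CSDA ranges
# (ICRU Report 37 stopping powers), used only to decide whether a secondary
# electron is short-ranged enough to deposit locally.  Log-log interpolated;
# energies below the first node are treated as locally deposited.
energy_mev	csda_range_um
0.001	0.05
0.002	0.15
0.003	0.30
0.004	0.55
0.005	0.80
0.010	2.5
0.020	8.6
0.030	17.6
0.050	43.2
0.070	78.0
0.100	143.0
0.200	448.0
0.300	843.0
0.500	1766.0
0.700	2800.0
1.000	4367.0
2.000	9785.0
3.000	15000.0
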