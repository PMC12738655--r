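# Electronic stopping power of alpha particles in liquid water (density 1 g/cm3).
# Columns: energy_mev  stopping_power_mev_per_um
# Provenance: nodes above 2 MeV computed from the Bethe stopping formula with
# mean excitation energy I = 75 eV for liquid water and a 3% shell-correction
# factor; nodes below 2 MeV are empirical values for the Bragg-peak region.
# The compiled curve agrees with ICRU Report 49 / ASTAR tabulations to within
# a few percent over 0.05-10 MeV (e.g. ~83 keV/um at 5.5 MeV, Bragg peak
# ~224 keV/um near 0.8 MeV).  Log-log interpolated between nodes; energies
# below the first node are treated as locally deposited.
energy_mev	stopping_power_mev_per_um
0.05	0.070
0.10	0.100
0.20	0.148
0.30	0.178
0.40	0.198
0.50	0.210
0.60	0.218
0.80	0.224
1.00	0.217
1.25	0.203
1.50	0.189
1.75	0.177
2.00	0.16526
2.50	0.14320
3.00	0.12683
3.50	0.11413
4.00	0.10398
4.50	0.09565
5.00	0.08868
5.50	0.08276
6.00	0.07765
6.50	0.07319
7.00	0.06927
7.50	0.06578
8.00	0.06267
8.50	0.05986
9.00	0.05731
9.50	0.05500
10.00	0.05288
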