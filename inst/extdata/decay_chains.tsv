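# Radioactive decay chains for the four targeted-alpha-therapy parents
# Ac-225, Ra-223, Pb-212 and At-211, down to (effective) stability.
# Columns: nuclide  half_life_s  probability  mode  daughter  emissions
#   probability : branch probability; per-nuclide branches sum to 1.
#   mode        : alpha | beta | electron_capture | stable
#   emissions   : semicolon list of kind:energy_MeV pairs emitted on this
#                 branch, or "-" for none.  Alpha fine-structure lines are
#                 separate branches; minor lines are folded into the dominant
#                 lines.  "beta" energies are MEAN beta energies (a single
#                 electron energy is drawn from an exponential of this mean
#                 at sampling time).  Recoil nuclei are generated by the
#                 sampler (E_recoil = E_alpha * m_alpha / m_daughter), not
#                 listed here.
# Provenance: condensed transcription of standard evaluated nuclear data
# (ENSDF-consistent branching ratios and line energies at the precision used).
nuclide	half_life_s	probability	mode	daughter	emissions
At-211	2.597e4	0.4180	alpha	Bi-207	alpha:5.8695
At-211	2.597e4	0.5820	electron_capture	Po-211	-
Po-211	0.516	0.9892	alpha	Pb-207	alpha:7.4503
Po-211	0.516	0.0055	alpha	Pb-207	alpha:6.8920;gamma:0.5694
Po-211	0.516	0.0053	alpha	Pb-207	alpha:6.5690;gamma:0.8971
Bi-207	9.97e8	1.0	electron_capture	Pb-207	gamma:0.5697;gamma:1.0637
Pb-207	Inf	1.0	stable	-	-
Ac-225	8.571e5	0.52	alpha	Fr-221	alpha:5.8301
Ac-225	8.571e5	0.28	alpha	Fr-221	alpha:5.7935
Ac-225	8.571e5	0.20	alpha	Fr-221	alpha:5.7323
Fr-221	286.2	0.84	alpha	At-217	alpha:6.3410
Fr-221	286.2	0.16	alpha	At-217	alpha:6.1260;gamma:0.2183
At-217	0.0323	1.0	alpha	Bi-213	alpha:7.0669
Bi-213	2736	0.9791	beta	Po-213	beta:0.435
Bi-213	2736	0.0209	alpha	Tl-209	alpha:5.8750
Po-213	4.2e-6	1.0	alpha	Pb-209	alpha:8.3760
Tl-209	129	1.0	beta	Pb-209	beta:0.660;gamma:1.5670
Pb-209	1.1755e4	1.0	beta	Bi-209	beta:0.198
Bi-209	Inf	1.0	stable	-	-
Ra-223	9.876e5	0.516	alpha	Rn-219	alpha:5.7162
Ra-223	9.876e5	0.252	alpha	Rn-219	alpha:5.6067;gamma:0.1541
Ra-223	9.876e5	0.090	alpha	Rn-219	alpha:5.7470
Ra-223	9.876e5	0.090	alpha	Rn-219	alpha:5.5398;gamma:0.2699
Ra-223	9.876e5	0.052	alpha	Rn-219	alpha:5.4338
Rn-219	3.96	0.796	alpha	Po-215	alpha:6.8193
Rn-219	3.96	0.129	alpha	Po-215	alpha:6.5531;gamma:0.2712
Rn-219	3.96	0.075	alpha	Po-215	alpha:6.4250;gamma:0.4019
Po-215	1.781e-3	1.0	alpha	Pb-211	alpha:7.3862
Pb-211	2166	1.0	beta	Bi-211	beta:0.450
Bi-211	128.4	0.8354	alpha	Tl-207	alpha:6.6229
Bi-211	128.4	0.1618	alpha	Tl-207	alpha:6.2782;gamma:0.3510
Bi-211	128.4	0.0028	beta	Po-211	beta:0.172
Tl-207	286.2	1.0	beta	Pb-207	beta:0.495
Pb-212	3.8304e4	1.0	beta	Bi-212	beta:0.102
Bi-212	3633	0.2516	alpha	Tl-208	alpha:6.0510
Bi-212	3633	0.1078	alpha	Tl-208	alpha:6.0898
Bi-212	3633	0.6406	beta	Po-212	beta:0.770
Po-212	3.0e-7	1.0	alpha	Pb-208	alpha:8.7849
Tl-208	183.2	1.0	beta	Pb-208	beta:0.560;gamma:2.6145
Pb-208	Inf	1.0	stable	-	-
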