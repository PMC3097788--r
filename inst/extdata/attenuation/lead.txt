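# Mass attenuation coefficients (photons, with coherent scattering)
# material: lead
# K-edge at 88 keV carried as a pair of bracketing grid points so that
# log-log interpolation does not smear the discontinuity.
# density_g_cm3: 11.30
# z_over_a: 0.39575
# columns: energy_keV  mu_over_rho_cm2_g
10     130.6
15     111.6
20     86.36
30     30.32
40     14.36
50     8.041
60     5.021
80     2.419
88.00  1.910
88.01  7.683
100    5.549
150    2.014
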