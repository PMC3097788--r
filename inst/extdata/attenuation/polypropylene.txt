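# Mass attenuation coefficients (photons, with coherent scattering)
# material: polypropylene
# Computed from elemental C/H values by mass fraction (C 0.85628, H 0.14372)
# density_g_cm3: 0.905
# z_over_a: 0.57034
# columns: energy_keV  mu_over_rho_cm2_g
10    2.0874
15    0.7452
20    0.4316
30    0.2707
40    0.2275
50    0.2084
60    0.1970
80    0.1823
100   0.1720
150   0.1534
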