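# kVp sweep of the 215 mm water phantom at 100 mA, 3 s
name = kvp_sweep_water
phantoms = water215
kvps = 80 100 120 140
ma = 100
offsets = 0
exposure_s = 3
n_photons = 1000000
seed = 7
assert = integrated_spr_decreasing_kvp
assert = scatter_two_peaks
assert = row_mirror_symmetry
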