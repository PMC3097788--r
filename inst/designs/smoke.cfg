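# reduced-photon smoke variant for quick runs
name = smoke
phantoms = water215
kvps = 80 140
ma = 100
offsets = 0
exposure_s = 3
n_photons = 100000
seed = 3
assert = integrated_spr_decreasing_kvp
assert = scatter_two_peaks
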