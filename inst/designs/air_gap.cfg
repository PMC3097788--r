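# axial off-centring sweep of the water phantom at 120 kVp / 100 mA:
# positive offsets move the phantom toward the detector (smaller air gap)
name = air_gap
phantoms = water215
kvps = 120
ma = 100
offsets = -100 -50 0 50 100
exposure_s = 3
n_photons = 1000000
seed = 13
assert = integrated_spr_increasing_offset
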