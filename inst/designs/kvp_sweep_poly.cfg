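# kVp sweep of the 300 mm polypropylene (obese-subject) phantom at 200 mA
name = kvp_sweep_poly
phantoms = poly300
kvps = 80 100 120 140
ma = 200
offsets = 0
exposure_s = 3
n_photons = 1000000
seed = 11
assert = integrated_spr_decreasing_kvp
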