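# Example acquisition configuration (units: mm, degrees).
# Geometry defaults to the studied 64-slice scanner; any key may be
# overridden.  Unknown keys are an error.

source_to_iso_mm      = 540
source_to_detector_mm = 950
blocker_plane_mm      = 160
fan_angle_deg         = 56

# standard phantom name (water215 | poly300 | none) and axial offset
phantom               = water215
phantom_offset_mm     = 0

# blocker layout: bars evenly spaced over the central 90% of the fan
n_bars                = 20
bar_width_mm          = 2
bar_thickness_mm      = 3
blocker_coverage      = 0.9

kvp                   = 120
ma                    = 100
exposure_s            = 3
n_photons             = 1000000
seed                  = 1
noise                 = off
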