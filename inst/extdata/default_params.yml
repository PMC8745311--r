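# Default analysis parameters, calibrated once against the synthetic
# generator at its default 600 px / 45-degree-field geometry and frozen.
# Lengths are pixels unless suffixed _dd (disc-diameter units).
quality:
  min_size: 128
  field_floor: 0.04          # luminance above this counts as inside the field
  min_field_fraction: 0.05   # else the image is called underexposed outright
  sharpness_min: 9.8e-05     # normalised high-frequency energy; calibrated so
                             # the blur sweep flips at the generator fail level
  illum_floor: 0.22          # luminance floor for "illuminated" pixels
  illuminated_min: 0.75
  saturation_max: 0.10
vessels:
  line_length: 17
  n_angles: 12
  threshold: 0.045           # black-top-hat response floor
  min_size: 60               # connected components smaller than this dropped
  hole_max: 300              # enclosed holes up to this area are filled
  field_erode: 8             # rim pixels excluded from the field
landmarks:
  smooth_sigma: 6
  disc_quantile: 0.985       # top-percentile binary mask on the green plane
  disc_min_contrast: 0.08    # required brightness of the disc peak over background
  disc_min_area_frac: 0.004  # plausible disc area, fraction of field area
  disc_max_area_frac: 0.10
  fovea_annulus_dd: [2.0, 3.0]
  fovea_half_angle: 30       # degrees about the disc horizontal
  fovea_window_frac: 0.5     # averaging window, fraction of disc radius
dark_lesions:
  close_size: 35             # grayscale closing brush (background estimate)
  c_min: 0.055               # minimum mean contrast vs local background
  a_min: 8
  a_max: 1600
  a_ma: 90                   # max area for a microaneurysm call
  circ_ma: 0.70              # min circularity for a microaneurysm call
  vessel_dilate: 5
  disc_exclude_dd: 0.75      # radius around disc centre excluded
  fovea_exclude_dd: 0.30     # radius around fovea excluded
  rim_exclude: 22            # rim ring beyond the vessel detector's reach
bright_lesions:
  fill_size: 31              # closing brush removing all dark structure first
  tophat_size: 35
  b_min: 0.055
  a_min: 8
  a_max: 2600
  disc_dilate_dd: 0.25       # disc circle dilation for exclusion
  g_min: 0.060               # boundary gradient splitting EX from CWS
merge:
  dedup_dd: 0.10             # per-eye centroid deduplication radius
grading:
  dme_dd: 1.0                # bright lesion within this of the fovea -> DME
  ung_precedence: dr_over_ung
generator:
  blur_fail: 4.0             # blur_sigma at/above this -> intended ungradable
  exposure_fail: 0.5         # exposure_scale below this -> ungradable
  vignette_fail: 0.75        # vignette_strength at/above this -> ungradable
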