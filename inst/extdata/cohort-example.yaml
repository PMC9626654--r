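# Example configuration for the synthetic lesion method-comparison pipeline.
# Every field is optional; anything omitted keeps the package default
# (see ?pipeline_config). Units: mm, mm^2, mm^3.

n_hearts: 10
n_lesions: 99

# Target dimension distributions (mean, SD) the cohort is drawn from,
# truncated to mutually consistent ranges.
dims:
  A: [9.008, 2.823]   # maximum depth
  B: [11.125, 2.801]  # maximum width
  C: [4.783, 1.648]   # depth of the maximum diameter
  D: [2.001, 0.872]   # estuary (surface opening)

wall_thickness: 16

# Irregular "steam pop" lesions: fraction of the cohort and modulation.
steam_pop:
  frac: 0.15
  amplitude: 0.5
  n_lobes: 3

# Thin-slice MRI-like acquisition and detection.
mri:
  slice_thickness: 1.0     # mm, slice axis
  in_plane: 0.390625       # mm/pixel (100 mm field of view / 256 matrix)
  border_width: 1.0        # dark border-zone rim around the core
  noise_sd: 0.02
  min_contrast: 0.15
  min_size: 5              # mm^3, smallest detectable component
  ghost_depth: 4.5         # lesions shallower than this render isointense

# Thick-slice pathology-like sectioning.
patho:
  thickness_range: [3, 5]  # mm slab thickness, drawn per heart
  in_plane: 0.390625
  # cut_aim: 0.5           # mm, uniform cut-aiming error (+/-); when
  #                        # omitted it defaults to half an MRI slice so
  #                        # both modalities sample the lesion plane with
  #                        # the same offset distribution
  min_face_area: 1.0       # mm^2, recognition threshold on the best face

# Observer emulation: per-dimension repeat noise and per-observer bias.
measurement:
  n_observers: 2
  n_repeats: 3
  repeat_sd: {A: 0.30, B: 0.30, C: 0.30, D: 0.15}
  observer_bias:
    - {A: -0.393, B: -0.550, C: -0.136, D: 0.057}
    - {A: 0.393, B: 0.550, C: 0.136, D: -0.057}

volume_cv: 0.03            # outlining noise of the point-by-point volume
alpha: 0.05
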