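# Example run configuration for the retrogate CLI / run_* functions.
# Any field left out falls back to the packaged default.
seed: 42
output_dir: retrogate-out
phantom:
  n_mice: 4
  amplitude: 1.2        # mm peak diaphragm excursion
  gasp_period: 22       # projections between gasp onsets
  gasp_duration: 5      # projections per gasp
  timing_jitter: 2      # SD of integer onset jitter
geometry:
  preset: desk          # or "full" for the published 1440-projection protocol
noise:
  i0: 10000             # photons per unattenuated detector pixel
  enabled: true
gating:
  rf: 0.2               # rejection fraction
  polarity: highest     # intensity-domain curves rise during a gasp
  roi_diameter: 8       # mm, sphere at each mouse's diaphragm
  coarse:
    factor: 2           # coarse preview voxel factor
    n_iterations: 8
recon:
  n_iterations: 30
  voxel_size: 0.4       # mm
  dims: [100, 60, 64]
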