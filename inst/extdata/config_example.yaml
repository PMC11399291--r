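# Example pipeline configuration. Paths are resolved relative to the
# working directory of the run.
samples: samples.csv
background: background.csv
scs: scs.csv          # optional; omit to skip exceedance screening
bioassay: bioassay.csv # optional; omit for an indices-only run
out_dir: results
elements: [As, Cd, Pb, Cr]
idw:
  power: 2
  grid_n: 100
  # buffer_radius: 800   # default: 2 x median nearest-neighbor distance
rules:
  pli_polluted_threshold: 1
  pvi_toxic_threshold: 80
seed: 1
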