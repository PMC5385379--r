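# Desk-scale demo configuration for run_pipeline(): a reduced imaging grid
# keeps the full per-animal simulate -> segment -> T1-fit -> Npx50 ->
# biochemistry chain to about a minute on one CPU.
seed: 21
period: 2-month
cine_matrix: [96, 96, 10]
cine_fov_mm: [30.0, 30.0, 3.125]
cine_frames: 3
branch_slice: 6
vfa_matrix: [64, 54, 4]
vfa_fov_mm: [30.0, 30.0, 2.0]
snr: 40.0
segmentation_fraction: 0.5
npx50_threshold: 0.5
rim_px: 2
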