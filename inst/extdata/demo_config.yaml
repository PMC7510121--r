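# Demo pipeline configuration: two conditions, small frames, oracle
# backend. Runs in a few minutes on one CPU.
conditions: [young, aged]
n_images: 10
shape: [512, 512]
tile: 256
stride: 128
score_min: 0.7
overlap_max: 0.30
iou_min: 0.3
backend: oracle
oracle:
  drop_rate: 0.05
  spurious_rate: 0.3
  score_mean: 0.9
  score_sd: 0.05
model: sde
k_folds: 5
n_droplets: 8
seed: 11
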