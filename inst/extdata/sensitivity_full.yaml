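# Full-scale sensitivity configuration: 10-mode mixture, sample sizes
# 20-100 by 10, census success 0.75-1, 1000 replicates per cell, 5000
# resamples per detection. Desk-scale runs use the same keys with smaller
# replicates/resamples. An alternative success grid of
# [0.80, 0.85, 0.90, 0.95, 1.00] is in common use; substitute it under
# `successes` if preferred.
modes: 10
mean_range: [0.5, 5.0]
sd_range: [0.05, 0.125]
sample_sizes: [20, 30, 40, 50, 60, 70, 80, 90, 100]
successes: [0.75, 0.80, 0.85, 0.90, 0.95, 1.00]
replicates: 1000
threshold: 0.90
resamples: 5000
bandwidth_increment: 0.001
mode: centers
seed: 1
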