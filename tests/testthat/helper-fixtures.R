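# Shared fixtures: the default ground truth (the paper-regime stated world)
# and one noisy dataset bundle reused across test files.
default_truth <- ground_truth()
default_bundle <- generate_dataset_bundle(default_truth, seed = 7)
noiseless_truth <- ground_truth(noise_cv = 0)
noiseless_bundle <- generate_dataset_bundle(noiseless_truth, seed = 3)
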