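# Example run configuration for runPipeline() / the reefchrono.R CLI:
# analyze the default synthetic Caribbean scenario, reef crest zone.
scenario: default
zone: CREST
millepora_included: true
engine: glmmTMB
nAGQ: 1
n_sim: 1000
B_boot: 1000
B_perm: 1000
alpha: 0.05
seed: 1
out_dir: reefchrono_out
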