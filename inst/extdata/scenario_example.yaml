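# Example scenario file for kinpref::read_scenario().
#
# Only fields present here override the defaults of default_scenario();
# everything omitted keeps its default. This example builds in a genuine
# kin preference so the pipeline has something to detect: a related-zone
# bias in the choice trials, extra social attraction toward siblings in
# the arenas, and a shared latent preference linking the experiments.

n_families: 24

exp1:
  trial_duration: 1800        # seconds
  frame_rate: 10              # frames per second
  bias_b: 0.65                # related-zone share of zone time (0.5 = none)
  p_zone:
    female: 0.68              # stationary zone share by focal sex
    male: 0.58
  switch_rate: 4              # expected zone/neutral switches per minute
  trait_effect: 0.1           # logit bias slope per mm body-length difference

exp2:
  n_arenas: 12
  duration: 1800
  base_attraction: 0.02       # uniform social pull between any two fish
  kin_attraction: 0.05        # added pull toward same-family individuals

exp3:
  sex_attraction:
    female: 0.03              # females shoal more than males
    male: 0.005
  kin_attraction: 0.05

latent:
  pref_sd: 1.0                # SD of the per-fish latent kin preference
  share: 0.8                  # fraction of latent variance shared across
                              # experiments (1 = perfectly persistent)
  gain: 0.5                   # how strongly the latent enters arena attraction
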