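# Example session configuration: a full evaluation of all four
# quadrants under the standardized conventions, answered by a simulated
# listener with a threshold midpoint of 0.03.
mode: full
quadrants: [I, II, III, IV]
seed: 42
readout_mode: sweet_point
conventions:
  gamma: 0.5
  beta: 100
  alpha_min: 0.001
  alpha_max: 0.1
  n_hypotheses: 100
  p_target: 0.809
  n_trials: 12
  initial_delta: 0.07
stimulus:
  duration: 4
  sample_rate: 44100
normalization:
  temperature: {target: 39, min: 35, max: 42}
  chlorine:    {target: 3,  min: 1,  max: 4}
observer:
  true_alpha: 0.03
  true_beta: 100
  lapse: 0
  seed: 7
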