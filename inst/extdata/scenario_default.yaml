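# Default synthetic-study scenario: 14 one-hour videos at 1 frame/s,
# half open-field activity tests, half novel-object exploration tests.
# Field names mirror simulation_params() / noise_params().
n_videos: 14
seed: 1
arena:
  width: 1280
  height: 768
  shelter_region: [0, 0, 160, 160]
  object_centroid: [900, 400]
simulation:
  duration: 3700          # analysed frames per one-hour video, at ~1 frame/s
  p_exit: 0.02            # hidden -> visible, per step
  p_enter: 0.02           # visible -> hidden, per step
  step_sigma: 20          # px, per-step displacement scale
  persistence: 0.7        # heading correlation
  start_state: hidden
  shelter_anchor: [100, 100]
noise:
  present_prob: [8, 2]    # Beta law of detector score, fish visible
  absent_prob: [2, 8]     # Beta law, fish hidden
  jitter_sigma: 5         # px, per-axis centroid noise
  outlier_prob: 0.01      # box relocation probability
  outlier_box_source: random_location
  box_halfwidth: 40       # px, emitted boxes are 80 x 50
  box_halfheight: 25
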