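# Deep-layer scenario: dives to a deep prey layer, bottoms below
# the 23 m gait split.
n_dives: 20
depth_meanlog: 3.8067  # log(45)
depth_sdlog: 0.2
depth_range: [30.0, 60.0]
duration_meanlog: 1.705  # log(5.5) min
p_feeding: 0.676
no_video_fraction: 0.25
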