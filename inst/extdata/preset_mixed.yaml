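# Mixed-depth scenario: dives straddle the 23 m gait split, full video
# coverage, even behaviour mix. Overrides applied on top of sim_config().
n_dives: 30
depth_meanlog: 3.1355  # log(23): ~half the dives cross the gait split
depth_sdlog: 0.5
p_feeding: 0.5
p_potential: 0.0
no_video_fraction: 0.0
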