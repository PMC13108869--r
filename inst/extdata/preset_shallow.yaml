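# Shallow-fjord scenario: tidally driven near-surface prey layer, all
# dives above the 23 m gait split.
n_dives: 20
depth_meanlog: 2.5649  # log(13)
depth_sdlog: 0.25
depth_range: [6.0, 22.0]
p_feeding: 0.676
no_video_fraction: 0.25
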