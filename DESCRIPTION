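Package: divekin
Title: Dive Segmentation and Kinematic Analysis of Whale-Borne Motion-Sensor Tags
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing high-resolution multi-sensor biologging
    records ("diaries") from whale-borne tags: reading and resampling
    accelerometer, gyroscope, magnetometer and depth channels; zero-phase
    Butterworth filtering and body-orientation (pitch, roll, heading)
    recovery; jerk, VeDBA and tag-jiggle swim-speed estimation; rule-based
    dive detection, phase segmentation and V/U/Square shape classification;
    fluke-stroke detection from the band-passed pitch-axis gyroscope with
    depth-stratified gait analysis; hierarchical matching of video-audit
    behaviour events onto dives; per-dive kinematic feature extraction; and
    binomial mixed-effects classification of feeding dives with AIC-based
    model comparison. A synthetic deployment simulator generates complete
    fake deployments with known truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    lme4,
    lmerTest,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
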