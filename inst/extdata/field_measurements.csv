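experiment,condition,alteration_deg,declination_deg,inclination_deg,intensity_ut,x_ut,y_ut,z_ut
1,before,180,0.0,56.0,48.095,26.824,-0.022,39.922
1,after,180,179.6,55.5,48.193,27.241,0.161,39.767
2,before,120,0.0,55.0,46.323,26.551,0.015,37.955
2,after,120,118.1,53.0,46.957,-13.130,25.035,37.505
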