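label,frequency_ghz,relative_intensity
d2_laser_lock,0.000000,1.0
ground_state_splitting,6.834683,0.6
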