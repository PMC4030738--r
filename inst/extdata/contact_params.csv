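stiffness_mpa_m,dissipation_s_m,static_friction,dynamic_friction,viscous_friction_s_m
1.86,1000,0.101,0.2,0.01
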