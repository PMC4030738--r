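muscle,fmax_n,l_opt_m,tendon_slack_m,fiber_ref_frac,vmax_lopt_per_s,r_hip_m,r_knee_m,r_ankle_m
soleus,2600,0.060,0.26,0.95,10,0,0,-0.040
gastrocnemius,1500,0.070,0.39,0.95,10,0,0.015,-0.035
vasti,3000,0.100,0.12,0.85,10,0,-0.030,0
rectus_femoris,800,0.110,0.32,0.90,10,0.030,-0.030,0
tibialis_anterior,700,0.070,0.22,0.95,10,0,0,0.035
hamstrings,2200,0.100,0.31,0.90,10,-0.050,0.025,0
iliopsoas,1200,0.100,0.12,1.00,10,0.040,0,0
gluteals,1800,0.150,0.11,0.92,10,-0.060,0,0
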