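muscle_group,profile,tau_l_s,tau_v_s,g_l,g_v
soleus,reference,0.075,0.040,0.1,0.59
gastrocnemius,reference,0.075,0.040,0.1,0.77
vasti,reference,0.050,0.040,0.1,0.37
rectus_femoris,reference,0.050,0.040,0.1,0.82
soleus,stroke,0.075,0.040,0.3,1.77
gastrocnemius,stroke,0.075,0.040,0.3,2.30
vasti,stroke,0.050,0.040,0.3,1.11
rectus_femoris,stroke,0.050,0.040,0.3,2.45
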