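v_rest: -70.0
v_thresh: -54.0
v_reset: -65.0
tau_m: 20.0
refractory: 5.0
dt: 0.1
g_ampa_sr: 70.0
g_ampa_slm: 0.8
g_nmda_sr: 1.0
g_nmda_slm: 1.0
g_gabaa_sr: 1.0
g_gabaa_slm: 1.0
g_gabab_sr: 0.15
g_gabab_slm: 1.0
g_gabab_soma: 0.12
g_car: 1.0
g_carh: 1.0
g_h: 1.0
g_cal: 1.0
g_can: 1.0
g_cat: 1.0
nmda_ampa_ratio_sr: 1.0
gabab_latency: 50.0
gabab_rise: 100.0
gabab_decay: 250.0
gabab_desens: 0.22
gabab_shunt: 0.55
subunit_half: 1.4
subunit_slope: 0.4
inh_half: 1.3
inh_slope: 0.45
plateau_threshold: 0.73
plateau_gain: 76.0
plateau_half: 1.0
plateau_duration: 140.0
plateau_adapt: 60.0
plateau_window: 40.0
priming_tau: 90.0
priming_base: 0.03
nmda_epsc_frac: 0.25
car_trig_w: 0.3
car_gate: 3.4
car_gate_tau: 30.0
h_rebound: 0.9
dend_coupling: 0.35
amp_w_base: 0.15
amp_w_nmda: 0.25
amp_w_car: 0.12
amp_w_carh: 0.3
amp_w_h: 0.18
epsp_rise: 1.5
epsp_decay: 5.0
slm_rise: 2.0
slm_decay: 25.0
e_inh: -90.0
noise_sd: 0.15
branch_sd: 0.25
ampa_comp: 0.35
gabaa_comp: 0.6
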