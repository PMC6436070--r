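name: ischemia
h: 0.5
t_end: 50.0
recirculation: yes
solver_method: jacobi
tensor_form: stated
sample_interval: 0.5
snapshot_times:
- 50.0
- 600.0
tol: 1.0e-08
safety: 0.25
seed: 1
p_epi: 2.0
p_endo: 0.0
p_sten: 1.4
stenosis_center_angle: 0.0
stenosis_half_width: 0.261799387799149
taper: abrupt
K1: 1.5
K2: 0.75
phi: 0.1
lambda: 0.25
lambda_f: 0.0
P: 0.03
k_e: 0.002
k_f: 0.0
k_ef: 0.0
D_i: 0.001
D_e: 0.001
sigma: 7.0
t_peak: 25.0
recirc_L: 25.0
recirc_h: 0.5
v_out: 1.0
D_out: 0.05
k: 0.02
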