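# Default model parameters (flat key -> value). Units: rates 1/d unless
# stated; concentrations g/cm^3; diffusivities cm^2/d; doses g/cm^3/d.
A: 1.41e-3
lambda_CCs: 6.0e-3
lambda_CCh: 3.26e-2
lambda_ChCc: 1.0e4
lambda_CsMP: 6.013e-5
lambda_CL2: 1.87e-8
mu_C: 0.03
mu_Cs0: 0.04
mu_Ch: 2.77
mu_MP: 13.86
mu_L2: 1.62e-5
mu_L2MP: 4.897e4     # cm^3/g/d
mu_MPL2: 100.2       # cm^3/g/d
mu_DCs: 3.0e2        # cm^3/g/d
mu_CsD: 1.0e3        # cm^3/g/d
delta_C: 8.64e-7
delta_Cc: 0.0
delta_MP: 6.6e-2
delta_L2: 4.78e-2
delta_D: 0.3782
K_L2: 1.7e-4
alpha_D: 2.0e6       # cm^3/g
alpha_U2: 0.05
alpha_w_MP: 2.5
alpha_w_L2: 2.5e-4
T_w_MP: 12           # years
T_w_L2: 12           # years
gamma_D: 1.52e-6
gamma_U2: 6.1e-7
mu_D: 5.55
omega_D: 0.01
h: 0.2               # cm
bc_leak_alpha: 4.9e-4  # 1/cm, calibrated (see calibrate_leak_rate)
days_per_year: 365
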