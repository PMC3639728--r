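h_rest_e: -68.13549999999999329
h_rest_i: -77.26019999999999754
tau_e: 138.36600000000001387
tau_i: 89.32070000000000221
h_eq_ee: -15.85270000000000046
h_eq_ei: 7.42279999999999962
h_eq_ie: -85.98959999999999582
h_eq_ii: -84.53629999999999711
Gamma_ee: 0.31269999999999998
Gamma_ei: 0.94259999999999999
Gamma_ie: 0.49469999999999997
Gamma_ii: 1.4121999999999999
gamma0_ee: 0.43930000000000002
gamma0_ei: 0.23499999999999999
gamma0_ie: 0.0791
gamma0_ii: 0.07820000000000001
eps_ee: 0.0
eps_ei: 0.0
eps_ie: 0.0
eps_ii: 0.0
N_alpha_ee: 4994.48599999999987631
N_alpha_ei: 2222.90599999999994907
N_beta_ee: 4582.06610000000000582
N_beta_ei: 4198.18289999999979045
N_beta_ie: 989.52809999999999491
N_beta_ii: 531.94190000000003238
v_ee: 0.1714
v_ei: 0.1714
Lambda_ee: 0.24329999999999999
Lambda_ei: 0.24329999999999999
S_max_e: 0.28010000000000002
S_max_i: 0.12280000000000001
mu_bar_e: -47.13640000000000185
mu_bar_i: -45.37510000000000332
sigma_e: 2.6120000000000001
sigma_i: 2.82940000000000014
p_ee: 3.60320000000000018
p_ei: 0.3639
p_ie: 0.0
p_ii: 0.0
sigmoid_slope: 1.41421356237309515

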