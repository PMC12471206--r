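# energy-balance model parameters (m.p.c., 1/min, bp, aa)
Ng = 3080000000
Q = 3804
A0 = 13100000000
tau = 1320
Nq = 431
NQ = 1300
NL = 6000
NS = 300
Naa = 5
Nnt = 15
chi_maxL = 840
chi_maxS = 840
K_chiL = 11000000
K_chiS = 11000000
K_L = 0.0022399999999999998
w_q = 4.6399999999999997
w_L = 1
w_S = 20
theta_q = 3800000000
theta_L = 3800000000
theta_S = 3800000000
gamma_maxq = 300
gamma_maxL = 300
K_gammaq = 25900
K_gammaL = 25900
k_bq = 4.9999999999999998e-08
k_bL = 4.9999999999999998e-08
k_uq = 0.01
k_uL = 0.01
k_subS = 4.9999999999999998e-08
k_subL = 5.0000000000000004e-06
r_tot = 9500000
lambda_a = 1.47
d_mq = 0.00115
d_mL = 0.00115
d_mS = 0.00115
d_cq = 0.0015499999999999999
d_cL = 0.0015499999999999999
d_q = 0.00056700000000000001
d_O1 = 0.00056700000000000001
d_bL = 0.00056700000000000001
d_bS = 0.00056700000000000001
lambda_L = 0.37
lambda_S = 1.1799999999999999
V_cell = 3700
a_wt = 5330000000
L_wt = 1064
S_wt = 13243
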