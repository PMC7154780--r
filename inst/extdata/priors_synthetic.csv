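parameter,lit_min,lit_max,domain_min,domain_max
alpha_c,0.04,0.07,0.001,0.2
y,0.43,0.51,0.2,0.8
k,0.4,0.7,0.1,1.5
full_can_age,0,6,0,50
t_min,-5,2,-20,10
t_opt,12,20,5,30
t_max,28,36,20,45
k_frost,0,1,0,1
coeff_cond,0.03,0.07,0.001,0.2
sw_const,0.55,0.8,0.1,0.95
sw_power,5,11,1,20
max_cond,0.015,0.025,0.001,0.1
min_cond,0,0.002,0,0.01
lai_gcx,2.5,4.5,0.5,10
bl_cond,0.1,0.3,0.01,1
max_intcptn,0.1,0.2,0,1
lai_max_intcptn,3,6,0.5,15
soil_cond,0.001,0.004,0.0001,0.02
fn0,0.3,1,0,1
fnn,0,2,0,5
m0,0,0.3,0,1
max_age,200,400,50,1000
n_age,2,6,0.5,15
r_age,0.8,1,0.1,1.5
f_calpha700,1.2,1.6,1.01,1.9
f_cg700,0.6,0.8,0.51,1
pfs2,0.5,1.5,0.05,3
pfs20,0.15,0.45,0.02,2
p_rx,0.6,0.9,0.1,0.99
p_rn,0.15,0.35,0.01,0.6
gamma_f0,0.0005,0.002,0.00001,0.01
gamma_f1,0.01,0.025,0.001,0.1
t_gamma_f,2,8,0.5,30
gamma_r,0.01,0.025,0.001,0.1
w_sx1000,200,400,50,1000
thin_power,1.3,1.7,0.5,3
m_f,0,0.3,0,1
m_r,0.1,0.3,0,1
m_s,0.1,0.3,0,1
a_ws,0.05,0.11,0.005,0.5
n_ws,2.3,2.7,1.5,3.5
a_h,2,4,0.5,10
n_hb,0.5,0.8,0.1,1.5
a_v,0.00005,0.0002,0.000001,0.001
n_vb,2.4,3.0,1.5,3.5
sla0,5,10,1,30
sla1,3,6,1,30
t_sla,2,6,0.5,20
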