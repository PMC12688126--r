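# GA scenario: fig1D_dynamics
name = fig1D_dynamics
kind = compare
variant = gahacr
target = GA20ox
seed = 1
t_end = 200
t_step = 0.5
param.ga12_synthesis = 1
param.k_ga20ox = 1
param.k_ga3ox = 1
param.ga_turnover = 0.10000000000000001
param.ga4_turnover = 0.20000000000000001
param.k_bind = 1
param.k_unbind = 0.20000000000000001
param.complex_turnover = 10
param.ga20ox_tx = 1
param.ga20ox_mrna_decay = 1
param.ga20ox_tl = 1
param.ga20ox_decay = 0.10000000000000001
param.K_ga20ox = 0.5
param.n_ga20ox = 2
param.ga3ox_tx = 1
param.ga3ox_mrna_decay = 1
param.ga3ox_tl = 1
param.ga3ox_decay = 0.10000000000000001
param.K_ga3ox = 0.5
param.n_ga3ox = 2
param.gid1_tx = 1
param.gid1_mrna_decay = 1
param.gid1_tl = 1
param.gid1_decay = 0.10000000000000001
param.K_gid1 = 0.5
param.n_gid1 = 2
param.della_tx = 1
param.della_mrna_decay = 1
param.della_tl = 1
param.della_decay = 0.10000000000000001
param.della_ga_decay = 5
param.K_della = 0.5
param.n_della = 2
param.hacr_tx = 1
param.hacr_tl = 1
param.hacr_mrna_decay = 1
param.hacr_protein_decay = 0.10000000000000001
param.hacr_ga_decay = 5
param.hacr_repstr = 1
param.hacr_rep_exponent = 1
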