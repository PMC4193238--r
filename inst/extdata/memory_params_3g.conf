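# Memory-model parameters, 3rd-generation kernel (bytes; fractions exact)
generation = 3g
m_n = 1100
m0_n = 1/3
mplus_n = 16
mempty_n = 0
m_stat_c = 48
m_stdp_c = 48
m0_c = 1/3
m1_c = 96
mgt1_c = 160
mempty_c = 0
beta = 0.8
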