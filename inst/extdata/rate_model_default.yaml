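k_at_ref: 0.00032
k_a2m_ref: 9.7e-06
fib_dependence: saturating
beta: 0.1
fib_ref: 2.9
at_nM_per_pct: 24.0
stoichiometric_depletion: yes
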