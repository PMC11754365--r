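# Competing hypotheses on the male conditional proportions eta_j = pi_2j / pi_+j
# of the 2x4 degrees-by-gender table (unconstrained failsafe added at run time).
H1: eta1 > {eta2, eta3, eta4}
H2: eta1 = eta2; eta3 > eta4
H3: eta1 > eta2 > eta3 > eta4
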