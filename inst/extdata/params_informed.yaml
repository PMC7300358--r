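# experimentally informed preset: ADE-up grows twice as fast and
# half-saturates at twice the concentration of LYS-up
r1: 1
r2: 2
K: 1
beta1: 0.1
beta2: 0.1
gamma1: 1
gamma2: 1
kcA: 2
kcL: 1
ro: 0
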