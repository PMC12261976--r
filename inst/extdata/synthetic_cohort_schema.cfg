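reward = Y
stage1.features = Z1.s1,Z2.s1,Z3.s1,Z4.s1,Z5.s1,Z6.s1,Z7.s1,Z8.s1,Z9.s1,Z10.s1,Z11.s1,Z12.s1,X1.s1,X2.s1,X3.s1
stage1.treatment = A1
stage1.propensity = p1
stage2.features = Z1.s2,Z2.s2,Z3.s2,Z4.s2,Z5.s2,Z6.s2,Z7.s2,Z8.s2,Z9.s2,Z10.s2,Z11.s2,Z12.s2,X1.s2,X2.s2,X3.s2,A1.s2
stage2.treatment = A2
stage2.propensity = p2
stage2.unpenalized = A1.s2
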