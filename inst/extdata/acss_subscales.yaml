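# Stand-in ACSS-MH item -> subscale map (the licensed instrument's true
# item membership is not public in this package's sources). Indices are
# 1-based, matching the acss_01..acss_31 columns. The first three subscales
# partition the 31 items; relational_base is an additional analysis subset.
individualized_care: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12]
system_responsiveness: [13, 14, 15, 16, 17, 18, 19, 20, 21, 22]
carer_responsiveness: [23, 24, 25, 26, 27, 28, 29, 30, 31]
relational_base: [1, 2, 3, 4, 5, 6, 13, 14, 15, 16]
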