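sex,cohort_A,cohort_B,cohort_C,cohort_D,cohort_E,cohort_F
Male,329,309,333,342,133,312
Female,290,253,312,245,100,223
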