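category,item,points
family_history,family_premature_cvd_or_high_ldl,1
family_history,family_xanthoma_or_child_high_ldl,2
clinical_history,premature_chd,2
clinical_history,premature_cerebral_peripheral,1
physical_exam,tendon_xanthomas,6
physical_exam,arcus_cornealis_under_45,4
ldl_c,ldl_ge_8p5,8
ldl_c,ldl_6p5_to_8p4,5
ldl_c,ldl_5p0_to_6p4,3
ldl_c,ldl_4p0_to_4p9,1
dna,causal_mutation,8
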