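variable,level,RFH,ALH,MALToma
group,n,54,28,43
sex,female,28,9,9
sex,male,26,19,34
laterality,unilateral,32,24,38
laterality,bilateral,22,4,5
site,orbital_soft_tissue,32,25,41
site,conjunctiva,0,2,8
site,lachrymal_gland,31,8,6
site,extraocular_muscle,14,11,12
site,other,5,2,2
symptom,periorbital_swelling,40,22,35
symptom,proptosis,46,22,37
symptom,impaired_vision,3,1,8
symptom,epiphora,2,1,4
symptom,pain,1,1,1
symptom,motility_impairment,4,0,10
symptom,ptosis,2,1,5
clonality,tested,35,17,21
clonality,clonal,0,8,18
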