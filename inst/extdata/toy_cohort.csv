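patient_id,tooth_id,age,gender,smoking,diabetes,pcr,jaw,tooth_type,furcation_class,bone_loss_raw,infrabony,abutment,lost_by_T2
p1,11,45,female,never,no,25.5,maxilla,anterior,single_rooted,<=20,shallow,none,0
p1,16,45,female,never,no,25.5,maxilla,molar,multi_FI,61-80,moderate,fixed,1
p1,24,45,female,never,no,25.5,maxilla,premolar,single_rooted,21-40,shallow,none,0
p2,36,67,male,active,yes,,mandible,molar,multi_no_FI,21-40,shallow,none,0
p2,41,67,male,active,yes,,mandible,anterior,single_rooted,41-60,shallow,none,0
p2,47,67,male,active,yes,,mandible,molar,multi_FI,>80,deep,removable,1
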