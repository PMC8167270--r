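innovation_id,region,criterion_or_attribute,value,source_type
sim_001,synthetic example,determinants_of_health,yes,
sim_001,synthetic example,innovativeness,yes,
sim_001,synthetic example,unavailability,no,
sim_001,synthetic example,corporate_social_irresponsibility,no,
sim_001,synthetic example,health_relevance,D,1
sim_001,synthetic example,elsis,,
sim_001,synthetic example,health_inequalities,A,3
sim_001,synthetic example,inclusiveness,C,1
sim_001,synthetic example,responsiveness,A,1
sim_001,synthetic example,level_intensity_of_care,A,1
sim_001,synthetic example,frugality,,
sim_001,synthetic example,business_model,A,3
sim_001,synthetic example,eco_responsibility,,
sim_002,synthetic example,determinants_of_health,yes,
sim_002,synthetic example,innovativeness,yes,
sim_002,synthetic example,unavailability,no,
sim_002,synthetic example,corporate_social_irresponsibility,yes,
sim_002,synthetic example,health_relevance,A,3
sim_002,synthetic example,elsis,C,2
sim_002,synthetic example,health_inequalities,,
sim_002,synthetic example,inclusiveness,C,3
sim_002,synthetic example,responsiveness,,
sim_002,synthetic example,level_intensity_of_care,A,1
sim_002,synthetic example,frugality,C,1
sim_002,synthetic example,business_model,C,1
sim_002,synthetic example,eco_responsibility,,
sim_003,synthetic example,determinants_of_health,yes,
sim_003,synthetic example,innovativeness,yes,
sim_003,synthetic example,unavailability,no,
sim_003,synthetic example,corporate_social_irresponsibility,no,
sim_003,synthetic example,health_relevance,A,1
sim_003,synthetic example,elsis,C,3
sim_003,synthetic example,health_inequalities,A,3
sim_003,synthetic example,inclusiveness,,
sim_003,synthetic example,responsiveness,A,2
sim_003,synthetic example,level_intensity_of_care,A,2
sim_003,synthetic example,frugality,B,1
sim_003,synthetic example,business_model,B,2
sim_003,synthetic example,eco_responsibility,C,1
sim_004,synthetic example,determinants_of_health,yes,
sim_004,synthetic example,innovativeness,yes,
sim_004,synthetic example,unavailability,no,
sim_004,synthetic example,corporate_social_irresponsibility,no,
sim_004,synthetic example,health_relevance,A,1
sim_004,synthetic example,elsis,,
sim_004,synthetic example,health_inequalities,A,1
sim_004,synthetic example,inclusiveness,B,1
sim_004,synthetic example,responsiveness,A,1
sim_004,synthetic example,level_intensity_of_care,A,2
sim_004,synthetic example,frugality,A,1
sim_004,synthetic example,business_model,A,1
sim_004,synthetic example,eco_responsibility,A,3
sim_005,synthetic example,determinants_of_health,yes,
sim_005,synthetic example,innovativeness,yes,
sim_005,synthetic example,unavailability,no,
sim_005,synthetic example,corporate_social_irresponsibility,no,
sim_005,synthetic example,health_relevance,A,3
sim_005,synthetic example,elsis,B,3
sim_005,synthetic example,health_inequalities,,
sim_005,synthetic example,inclusiveness,,
sim_005,synthetic example,responsiveness,A,1
sim_005,synthetic example,level_intensity_of_care,A,1
sim_005,synthetic example,frugality,A,1
sim_005,synthetic example,business_model,B,1
sim_005,synthetic example,eco_responsibility,,
sim_006,synthetic example,determinants_of_health,yes,
sim_006,synthetic example,innovativeness,yes,
sim_006,synthetic example,unavailability,yes,
sim_006,synthetic example,corporate_social_irresponsibility,no,
sim_006,synthetic example,health_relevance,A,3
sim_006,synthetic example,elsis,C,1
sim_006,synthetic example,health_inequalities,A,1
sim_006,synthetic example,inclusiveness,A,3
sim_006,synthetic example,responsiveness,A,2
sim_006,synthetic example,level_intensity_of_care,A,3
sim_006,synthetic example,frugality,B,1
sim_006,synthetic example,business_model,A,3
sim_006,synthetic example,eco_responsibility,,
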