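"condition_id","label","group","acute","event_af_computable","icd10","rr_current","rr_former","case_fatality","disability_weight","mean_duration_years","annual_direct_cost","informal_care_hours_per_year","mortality_scale_male","mortality_scale_female"
"ami","Acute myocardial infarction","cardiovascular",TRUE,TRUE,"I210-I229",2.3,1.65,0.18,0.12,0.5,12000,100,1,1
"coronary_non_ami","Ischemic heart disease (non-AMI)","cardiovascular",TRUE,TRUE,"I200-I209",2,1.5,0.05,0.08,1,8000,50,1,1
"heart_non_ischemic","Non-ischemic heart disease","cardiovascular",FALSE,FALSE,"I30-I52",1.6,1.3,0,0.1,8,4000,150,1,1
"stroke","Stroke","stroke",TRUE,TRUE,"I60;I61;I63;I64;I620;I621;I629;I678;I679;I690-I694;I698",1.9,1.45,0.19,0.32,3,9000,800,1,1
"pneumonia","Pneumonia","pneumonia",TRUE,TRUE,"J100-J189",2.2,1.6,0.12,0.13,0.2,3000,40,1,1
"copd","COPD","copd",FALSE,TRUE,"J400-J439;J44X",10,5.5,0,0.19,10,3600,600,1,1
"lung_cancer","Lung cancer","lung_cancer",FALSE,TRUE,"C330-C349",25,13,0,0.29,2.5,25000,500,1,1
"oropharyngeal_cancer","Oropharyngeal cancer","other_cancers",FALSE,TRUE,"C000-C009;C140;C142;C148",6,3.5,0,0.29,3,18000,300,1,1
"esophageal_cancer","Esophageal cancer","other_cancers",FALSE,TRUE,"C150-C159",4.5,2.75,0,0.29,1.8,20000,350,1,1
"stomach_cancer","Stomach cancer","other_cancers",FALSE,TRUE,"C160-C169",1.8,1.4,0,0.29,2.2,18000,300,1,1
"pancreatic_cancer","Pancreatic cancer","other_cancers",FALSE,TRUE,"C250-C259",2.2,1.6,0,0.29,1.2,22000,350,1,1
"renal_cancer","Kidney cancer","other_cancers",FALSE,TRUE,"C64X-C65X",1.7,1.35,0,0.29,3.5,20000,250,1,1
"laryngeal_cancer","Laryngeal cancer","other_cancers",FALSE,TRUE,"C320-C329",14,7.5,0,0.23,4,16000,250,1,1
"cervical_cancer","Cervical cancer","other_cancers",FALSE,TRUE,"C530-C539",1.8,1.4,0,0.29,4,15000,250,1,1
"bladder_cancer","Bladder cancer","other_cancers",FALSE,TRUE,"C670-C679",2.8,1.9,0,0.2,5,14000,200,1,1
"leukemia","Leukemia","other_cancers",FALSE,TRUE,"C920",1.5,1.25,0,0.26,2.5,30000,400,1,1
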