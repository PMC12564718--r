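factor_id,name,synonyms
F01,weight loss,weight loss|losing weight|lost weight
F02,poor appetite,poor appetite|reduced appetite|appetite loss
F03,poor oral intake,poor oral intake|reduced intake|low food intake
F04,food refusal,food refusal|refusing meals|refused food
F05,dysphagia,dysphagia|swallowing difficulty|difficulty swallowing
F06,chewing difficulty,chewing difficulty|difficulty chewing
F07,nausea,nausea|feeling nauseous
F08,vomiting,vomiting|emesis
F09,diarrhoea,diarrhoea|loose stools
F10,constipation,constipation
F11,dehydration,dehydration|poor fluid intake
F12,dementia,dementia
F13,cognitive impairment,cognitive impairment|confusion
F14,depression,depression|low mood
F15,anxiety,anxiety
F16,cancer,cancer|malignancy
F17,pressure injury,pressure injury|pressure ulcer
F18,wound,wound|skin tear
F19,infection,infection|sepsis
F20,fever,fever|febrile
F21,pain,pain
F22,fatigue,fatigue|lethargy
F23,frailty,frailty|frail
F24,immobility,immobility|bedbound
F25,falls,falls|recent fall
F26,tremor,tremor
F27,stroke,stroke|cva
F28,parkinsons disease,parkinsons disease|parkinsons
F29,copd,copd|chronic lung disease
F30,heart failure,heart failure|cardiac failure
F31,renal disease,renal disease|kidney disease
F32,liver disease,liver disease
F33,diabetes,diabetes|diabetic
F34,thyroid disorder,thyroid disorder|hypothyroidism
F35,malabsorption,malabsorption
F36,gastric reflux,gastric reflux|gord
F37,abdominal pain,abdominal pain|stomach pain
F38,early satiety,early satiety|fills quickly
F39,taste changes,taste changes|altered taste
F40,dry mouth,dry mouth|xerostomia
F41,mouth ulcers,mouth ulcers|oral ulcers
F42,dental pain,dental pain|toothache
F43,ill fitting dentures,ill fitting dentures|loose dentures
F44,polypharmacy,polypharmacy
F45,medication side effects,medication side effects|drug side effects
F46,low bmi,low bmi|underweight
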