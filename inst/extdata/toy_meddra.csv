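pt,pt_code,soc,soc_code
FEBRILE NEUTROPENIA,10016288,Blood and lymphatic system disorders,10005329
NEUTROPENIA,10029354,Blood and lymphatic system disorders,10005329
THROMBOCYTOPENIA,10043554,Blood and lymphatic system disorders,10005329
ANAEMIA,10002034,Blood and lymphatic system disorders,10005329
PANCYTOPENIA,10033661,Blood and lymphatic system disorders,10005329
CYTOPENIA,10066274,Blood and lymphatic system disorders,10005329
LEUKOPENIA,10024384,Blood and lymphatic system disorders,10005329
MYELOSUPPRESSION,10028584,Blood and lymphatic system disorders,10005329
BONE MARROW FAILURE,10065553,Blood and lymphatic system disorders,10005329
PNEUMONIA,10035664,Infections and infestations,10021881
SEPSIS,10040047,Infections and infestations,10021881
SEPTIC SHOCK,10040070,Infections and infestations,10021881
INFECTION,10021789,Infections and infestations,10021881
CELLULITIS,10007882,Infections and infestations,10021881
RESPIRATORY TRACT INFECTION,10062352,Infections and infestations,10021881
URINARY TRACT INFECTION,10046571,Infections and infestations,10021881
FUNGAL INFECTION,10017533,Infections and infestations,10021881
BACTERAEMIA,10003997,Infections and infestations,10021881
PROTOTHECOSIS,10036936,Infections and infestations,10021881
DEATH,10011906,General disorders and administration site conditions,10018065
PYREXIA,10037660,General disorders and administration site conditions,10018065
FATIGUE,10016256,General disorders and administration site conditions,10018065
DISEASE PROGRESSION,10061818,General disorders and administration site conditions,10018065
THERAPY NON-RESPONDER,10043414,General disorders and administration site conditions,10018065
INJECTION SITE REACTION,10022095,General disorders and administration site conditions,10018065
MULTIPLE ORGAN DYSFUNCTION SYNDROME,10077361,General disorders and administration site conditions,10018065
GENERAL PHYSICAL HEALTH DETERIORATION,10049438,General disorders and administration site conditions,10018065
ACUTE MYELOID LEUKAEMIA,10000880,"Neoplasms benign, malignant and unspecified (incl cysts and polyps)",10029104
MYELODYSPLASTIC SYNDROME,10028533,"Neoplasms benign, malignant and unspecified (incl cysts and polyps)",10029104
MYELODYSPLASTIC SYNDROME TRANSFORMATION,10079230,"Neoplasms benign, malignant and unspecified (incl cysts and polyps)",10029104
TRANSFORMATION TO ACUTE MYELOID LEUKAEMIA,10077302,"Neoplasms benign, malignant and unspecified (incl cysts and polyps)",10029104
ACUTE MYELOID LEUKAEMIA RECURRENT,10000890,"Neoplasms benign, malignant and unspecified (incl cysts and polyps)",10029104
CHRONIC MYELOMONOCYTIC LEUKAEMIA,10009013,"Neoplasms benign, malignant and unspecified (incl cysts and polyps)",10029104
LEUKAEMIA CUTIS,10024324,"Neoplasms benign, malignant and unspecified (incl cysts and polyps)",10029104
TUMOUR LYSIS SYNDROME,10045170,Metabolism and nutrition disorders,10027433
HYPOKALAEMIA,10021015,Metabolism and nutrition disorders,10027433
DECREASED APPETITE,10061428,Metabolism and nutrition disorders,10027433
NAUSEA,10028813,Gastrointestinal disorders,10017947
VOMITING,10047700,Gastrointestinal disorders,10017947
DIARRHOEA,10012735,Gastrointestinal disorders,10017947
CONSTIPATION,10010774,Gastrointestinal disorders,10017947
RESPIRATORY FAILURE,10038695,"Respiratory, thoracic and mediastinal disorders",10038738
INTERSTITIAL LUNG DISEASE,10022611,"Respiratory, thoracic and mediastinal disorders",10038738
PNEUMONITIS,10035742,"Respiratory, thoracic and mediastinal disorders",10038738
PLEURAL EFFUSION,10035598,"Respiratory, thoracic and mediastinal disorders",10038738
DYSPNOEA,10013968,"Respiratory, thoracic and mediastinal disorders",10038738
CARDIAC FAILURE,10007554,Cardiac disorders,10007541
PERICARDITIS,10034484,Cardiac disorders,10007541
ATRIAL FIBRILLATION,10003658,Cardiac disorders,10007541
PLATELET COUNT DECREASED,10035528,Investigations,10022891
WHITE BLOOD CELL COUNT DECREASED,10047942,Investigations,10022891
NEUTROPHIL COUNT DECREASED,10029366,Investigations,10022891
HAEMOGLOBIN DECREASED,10018884,Investigations,10022891
BLAST CELL COUNT INCREASED,10065869,Investigations,10022891
CEREBRAL HAEMORRHAGE,10008111,Nervous system disorders,10029205
FLT3 GENE MUTATION,10068614,"Congenital, familial and genetic disorders",10010331
RENAL FAILURE,10038435,Renal and urinary disorders,10038359
RASH,10037844,Skin and subcutaneous tissue disorders,10040785
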