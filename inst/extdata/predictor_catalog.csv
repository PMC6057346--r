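predictor,value_label,risk_level
Site of insertion,No Risk,No Risk
Site of insertion,subclavian,Low Risk
Site of insertion,jugular,Mild Risk
Site of insertion,femoral,High Risk
Rewire,No Risk,No Risk
Rewire,Yes,High Risk
Status of Procedure,No Risk,No Risk
Status of Procedure,Elective,Low Risk
Status of Procedure,Emergency,High Risk
Co-morbidities,No Risk,No Risk
Co-morbidities,Sickle Cell Anemia,High Risk
Co-morbidities,BA(Bronchial Asthma),High Risk
Co-morbidities,Meningitis,High Risk
Co-morbidities,Pulmonary Tuberculosis,High Risk
Co-morbidities,Myocardial Infacrtion,High Risk
Co-morbidities,Chronic Liver Disease,High Risk
Co-morbidities,Malignancy,High Risk
Co-morbidities,HTN(Hypertension),High Risk
Co-morbidities,DM(Diabetes Mellitus),High Risk
Co-morbidities,Cerebral Infarction,High Risk
Co-morbidities,Heart Disease,High Risk
Compliant to Central Line Insertion & Maintenance bundle,Yes,No Risk
Compliant to Central Line Insertion & Maintenance bundle,No,High Risk
Length of Stay,No Risk,No Risk
Length of Stay,Less than equal 14 days,Mild Risk
Length of Stay,More than 14 days,High Risk
Parenteral nutrition,No Risk,No Risk
Parenteral nutrition,Yes,High Risk
Antimicrobial usage,No Risk,No Risk
Antimicrobial usage,Yes,High Risk
Renal failure,No Risk,No Risk
Renal failure,Yes,High Risk
Age,No Risk,No Risk
Age,Adult,Low Risk
Age,New Born,Mild Risk
Age,Elderly,High Risk
Age,Premature,High Risk
Surgical procedure,No Risk,No Risk
Surgical procedure,Yes,High Risk
Sex,No Risk,No Risk
Sex,Female,Low Risk
Sex,Male,High Risk
Duration of device use,No Risk,No Risk
Duration of device use,1 to 5 days,Low Risk
Duration of device use,6 to 10 days,Mild Risk
Duration of device use,More than 10 days,High Risk
Transfer from other hospital,No Risk,No Risk
Transfer from other hospital,Yes,High Risk
Transfer from other unit within the hospital,No Risk,No Risk
Transfer from other unit within the hospital,Yes,High Risk
Co-existing infection,No Risk,No Risk
Co-existing infection,Yes,High Risk
Temperature,No Risk,No Risk
Temperature,Yes,High Risk
APACHE Score,No Risk,No Risk
APACHE Score,0 to 14,Low Risk
APACHE Score,15-29,Mild Risk
APACHE Score,>= 30,High Risk
Ventilated,No Risk,No Risk
Ventilated,Yes,High Risk
Birth weight,No Risk,No Risk
Birth weight,>2500,Low Risk
Birth weight,1000-1500,Mild Risk
Birth weight,1501-2500,Mild Risk
Birth weight,<= 750 gm,High Risk
Birth weight,750-1000 gm,High Risk
Nasal CPAP,No Risk,No Risk
Nasal CPAP,Yes,High Risk
Blood Transfusion,No Risk,No Risk
Blood Transfusion,Yes,High Risk
Trauma,No Risk,No Risk
Trauma,Yes,High Risk
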