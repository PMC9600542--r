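report_id,drug,event_pt,continent,age_group,sex,serious,notifier
R01,salbutamol,Cough,Europe,≥75 years,Male,Yes,Consumer/Non-Health Professional
R01,salbutamol,Drug ineffective,Europe,≥75 years,Male,Yes,Consumer/Non-Health Professional
R01,salbutamol,Pruritus,Europe,≥75 years,Male,Yes,Consumer/Non-Health Professional
R02,cetirizine,Asthma,Europe,18–44 years,Female,Yes,Physician
R03,salbutamol,Headache,Asia,Unknown,Female,No,Consumer/Non-Health Professional
R03,salbutamol,Injection site reaction,Asia,Unknown,Female,No,Consumer/Non-Health Professional
R03,salbutamol,Pruritus,Asia,Unknown,Female,No,Consumer/Non-Health Professional
R04,fluticasone,Dizziness,Americas,Unknown,Female,No,Other Health Professional
R04,salbutamol,Dizziness,Americas,Unknown,Female,No,Other Health Professional
R05,montelukast,Pyrexia,Americas,45–65 years,Female,No,Physician
R06,fluticasone,Drug ineffective,Americas,45–65 years,Female,No,Physician
R06,fluticasone,Dyspnoea,Americas,45–65 years,Female,No,Physician
R06,fluticasone,Fatigue,Americas,45–65 years,Female,No,Physician
R07,fluticasone,Chest discomfort,Asia,45–65 years,Female,No,Consumer/Non-Health Professional
R07,fluticasone,Dizziness,Asia,45–65 years,Female,No,Consumer/Non-Health Professional
R07,fluticasone,Drug ineffective,Asia,45–65 years,Female,No,Consumer/Non-Health Professional
R07,fluticasone,Pain,Asia,45–65 years,Female,No,Consumer/Non-Health Professional
R07,prednisolone,Chest discomfort,Asia,45–65 years,Female,No,Consumer/Non-Health Professional
R07,prednisolone,Dizziness,Asia,45–65 years,Female,No,Consumer/Non-Health Professional
R07,prednisolone,Drug ineffective,Asia,45–65 years,Female,No,Consumer/Non-Health Professional
R07,prednisolone,Pain,Asia,45–65 years,Female,No,Consumer/Non-Health Professional
R08,mepolizumab,Urticaria,Asia,Unknown,Female,No,Other Health Professional
R08,prednisolone,Urticaria,Asia,Unknown,Female,No,Other Health Professional
R09,cetirizine,Malaise,Americas,45–65 years,Female,Yes,Other Health Professional
R09,cetirizine,Urticaria,Americas,45–65 years,Female,Yes,Other Health Professional
R10,prednisolone,Chest discomfort,Americas,18–44 years,Female,Yes,Physician
R10,prednisolone,Cough,Americas,18–44 years,Female,Yes,Physician
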