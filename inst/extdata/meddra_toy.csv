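pt,primary_soc,hlt,hlgt
Ear pain,Ear and labyrinth disorders,Ear disorders NEC,External ear disorders (excl congenital)
Ear discomfort,Ear and labyrinth disorders,Ear disorders NEC,External ear disorders (excl congenital)
Otorrhoea,Ear and labyrinth disorders,Ear disorders NEC,External ear disorders (excl congenital)
Ear pruritus,Ear and labyrinth disorders,Ear disorders NEC,External ear disorders (excl congenital)
Ear congestion,Ear and labyrinth disorders,Ear disorders NEC,External ear disorders (excl congenital)
Ear swelling,Ear and labyrinth disorders,Ear disorders NEC,External ear disorders (excl congenital)
Ear disorder,Ear and labyrinth disorders,Ear disorders NEC,External ear disorders (excl congenital)
Tympanic membrane perforation,Ear and labyrinth disorders,Tympanic membrane disorders,Middle ear disorders (excl congenital)
Deafness unilateral,Ear and labyrinth disorders,Hearing losses,Hearing disorders
Vertigo positional,Ear and labyrinth disorders,Vertigos,Inner ear disorders
Middle ear effusion,Ear and labyrinth disorders,Middle ear disorders NEC,Middle ear disorders (excl congenital)
Meniere's disease,Ear and labyrinth disorders,Inner ear disorders NEC,Inner ear disorders
Cerumen impaction,Ear and labyrinth disorders,External ear disorders NEC,External ear disorders (excl congenital)
Tympanic membrane disorder,Ear and labyrinth disorders,Tympanic membrane disorders,Middle ear disorders (excl congenital)
Tympanic membrane scarring,Ear and labyrinth disorders,Tympanic membrane disorders,Middle ear disorders (excl congenital)
Eustachian tube obstruction,Ear and labyrinth disorders,Eustachian tube disorders,Middle ear disorders (excl congenital)
Eustachian tube disorder,Ear and labyrinth disorders,Eustachian tube disorders,Middle ear disorders (excl congenital)
Eosinophilic granulomatosis with polyangiitis,Vascular disorders,Vasculitides,Vascular inflammations
Eosinophilia,Blood and lymphatic system disorders,Eosinophilic disorders,White blood cell disorders
Eosinophil count increase,Investigations,White blood cell analyses,Haematology investigations (incl blood groups)
Eosinophilic pneumonia,"Respiratory, thoracic and mediastinal disorders",Eosinophilic pneumonias,Lower respiratory tract disorders (excl obstruction and infection)
Eosinophilic oesophagitis,Gastrointestinal disorders,Oesophagitis and oesophageal ulceration,Oesophageal conditions
Hypereosinophilic syndrome,Blood and lymphatic system disorders,Eosinophilic disorders,White blood cell disorders
Eosinophilic pneumonia chronic,"Respiratory, thoracic and mediastinal disorders",Eosinophilic pneumonias,Lower respiratory tract disorders (excl obstruction and infection)
Eosinophil count abnormal,Investigations,White blood cell analyses,Haematology investigations (incl blood groups)
Eosinophilic bronchitis,"Respiratory, thoracic and mediastinal disorders",Bronchial conditions NEC,Bronchial disorders (excl neoplasms)
Drug ineffective,General disorders and administration site conditions,Therapeutic and nontherapeutic responses,Therapeutic and nontherapeutic effects (excl toxicity)
Headache,Nervous system disorders,Headaches NEC,Headaches
Dyspnoea,"Respiratory, thoracic and mediastinal disorders",Breathing abnormalities,Respiratory disorders NEC
Asthma,"Respiratory, thoracic and mediastinal disorders",Bronchospasm and obstruction,Bronchial disorders (excl neoplasms)
Urticaria,Skin and subcutaneous tissue disorders,Urticarias,Epidermal and dermal conditions
Fatigue,General disorders and administration site conditions,Asthenic conditions,General system disorders NEC
Cough,"Respiratory, thoracic and mediastinal disorders",Coughing and associated symptoms,Respiratory disorders NEC
Nausea,Gastrointestinal disorders,Nausea and vomiting symptoms,Gastrointestinal signs and symptoms
Dizziness,Nervous system disorders,Neurological signs and symptoms NEC,Neurological disorders NEC
Pruritus,Skin and subcutaneous tissue disorders,Pruritus NEC,Epidermal and dermal conditions
Rash,Skin and subcutaneous tissue disorders,Rashes eruptions and exanthems NEC,Epidermal and dermal conditions
Injection site reaction,General disorders and administration site conditions,Injection site reactions,Administration site reactions
Injection site pain,General disorders and administration site conditions,Injection site reactions,Administration site reactions
Arthralgia,Musculoskeletal and connective tissue disorders,Joint related signs and symptoms,Joint disorders
Pyrexia,General disorders and administration site conditions,Febrile disorders,Body temperature conditions
Anaphylactic reaction,Immune system disorders,Anaphylactic and anaphylactoid responses,Allergic conditions
Alopecia,Skin and subcutaneous tissue disorders,Alopecias,Epidermal and dermal conditions
Malaise,General disorders and administration site conditions,Feelings and sensations NEC,General system disorders NEC
Pain,General disorders and administration site conditions,Pain and discomfort NEC,General system disorders NEC
Vomiting,Gastrointestinal disorders,Nausea and vomiting symptoms,Gastrointestinal signs and symptoms
Oedema peripheral,General disorders and administration site conditions,Oedema NEC,General system disorders NEC
Chest discomfort,General disorders and administration site conditions,Pain and discomfort NEC,General system disorders NEC
Wheezing,"Respiratory, thoracic and mediastinal disorders",Breathing abnormalities,Respiratory disorders NEC
Insomnia,Psychiatric disorders,Disturbances in initiating and maintaining sleep,Sleep disorders and disturbances
Hypersensitivity,Immune system disorders,Allergic conditions NEC,Allergic conditions
Myalgia,Musculoskeletal and connective tissue disorders,Muscle related signs and symptoms NEC,Muscle disorders
Sinusitis,Infections and infestations,Upper respiratory tract infections,Infections - pathogen unspecified
Migraine,Nervous system disorders,Migraine headaches,Headaches
Paraesthesia,Nervous system disorders,Paraesthesias and dysaesthesias,Neurological disorders NEC
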