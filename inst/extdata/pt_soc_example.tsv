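pt_name	soc_name	soc_code	is_primary_soc
Anemia	Blood and lymphatic system disorders	10005329	TRUE
Anaemia	Blood and lymphatic system disorders	10005329	TRUE
Myelodysplastic syndrome	Blood and lymphatic system disorders	10005329	TRUE
Thrombocytopenia	Blood and lymphatic system disorders	10005329	TRUE
Acute myeloid leukemia	Blood and lymphatic system disorders	10005329	TRUE
Pancytopenia	Blood and lymphatic system disorders	10005329	TRUE
Bone marrow failure	Blood and lymphatic system disorders	10005329	TRUE
Hematotoxicity	Blood and lymphatic system disorders	10005329	TRUE
Myelosuppression	Blood and lymphatic system disorders	10005329	TRUE
Metastases to lymph nodes	Blood and lymphatic system disorders	10005329	TRUE
Leukemia	Blood and lymphatic system disorders	10005329	TRUE
Cytopenia	Blood and lymphatic system disorders	10005329	TRUE
Hemolytic anemia	Blood and lymphatic system disorders	10005329	TRUE
Acute leukemia	Blood and lymphatic system disorders	10005329	TRUE
Blood disorder	Blood and lymphatic system disorders	10005329	TRUE
Anemia macrocytic	Blood and lymphatic system disorders	10005329	TRUE
Lymphangiosis carcinomatosa	Blood and lymphatic system disorders	10005329	TRUE
Bone marrow disorder	Blood and lymphatic system disorders	10005329	TRUE
Macrocytosis	Blood and lymphatic system disorders	10005329	TRUE
Aplasia pure red cell	Blood and lymphatic system disorders	10005329	TRUE
Myeloid leukemia	Blood and lymphatic system disorders	10005329	TRUE
Lymphadenopathy	Blood and lymphatic system disorders	10005329	TRUE
Petechiae	Blood and lymphatic system disorders	10005329	TRUE
Lymphoedema	Blood and lymphatic system disorders	10005329	TRUE
Platelet disorder	Blood and lymphatic system disorders	10005329	TRUE
Increased tendency to bruise	Blood and lymphatic system disorders	10005329	TRUE
White blood cell disorder	Blood and lymphatic system disorders	10005329	TRUE
Transfusion reaction	Blood and lymphatic system disorders	10005329	TRUE
Red blood cell abnormality	Blood and lymphatic system disorders	10005329	TRUE
Abdominal lymphadenopathy	Blood and lymphatic system disorders	10005329	TRUE
Metastases to spleen	Blood and lymphatic system disorders	10005329	TRUE
Neutropenia	Blood and lymphatic system disorders	10005329	TRUE
Febrile neutropenia	Blood and lymphatic system disorders	10005329	TRUE
Leukopenia	Blood and lymphatic system disorders	10005329	TRUE
Anaemia	Neoplasms benign, malignant and unspecified	10029104	FALSE
Thrombocytopenia	Investigations	10022891	FALSE
Nausea	Gastrointestinal disorders	10017947	TRUE
Diarrhoea	Gastrointestinal disorders	10017947	TRUE
Vomiting	Gastrointestinal disorders	10017947	TRUE
Fatigue	General disorders and administration site conditions	10018065	TRUE
Pyrexia	General disorders and administration site conditions	10018065	TRUE
Headache	Nervous system disorders	10029205	TRUE
Dizziness	Nervous system disorders	10029205	TRUE
Rash	Skin and subcutaneous tissue disorders	10040785	TRUE
Dyspnoea	Respiratory, thoracic and mediastinal disorders	10038738	TRUE
Arthralgia	Musculoskeletal and connective tissue disorders	10028395	TRUE
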