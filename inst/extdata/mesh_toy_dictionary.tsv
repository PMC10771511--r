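term	tree_number	name
protein	D12.776	Proteins
proteins	D12.776	Proteins
c-reactive protein	D12.776.124.486	C-Reactive Protein
hemoglobin	D12.776.422.316	Hemoglobins
hemoglobin a1c	D12.776.422.316.762	Glycated Hemoglobin
hba1c	D12.776.422.316.762	Glycated Hemoglobin
fatty acids	D10.251	Fatty Acids
cholesterol	D10.570.938	Cholesterol
ldl-c	D10.570.938.250	Cholesterol, LDL
ldl cholesterol	D10.570.938.250	Cholesterol, LDL
hdl-c	D10.570.938.125	Cholesterol, HDL
triglycerides	D10.808	Triglycerides
glucose	D09.400.410	Glucose
blood glucose	D09.400.410.250	Blood Glucose
insulin	D06.472.699.587.466	Insulin
creatinine	D03.383.533.320	Creatinine
bilirubin	D03.549.909.500	Bilirubin
interleukin-6	D12.644.276.374.465	Interleukin-6
cytokine	D12.644.276	Cytokines
albumin	D12.776.034	Albumins
ferritin	D12.776.422.314	Ferritins
cortisol	D04.210.500.745.432	Hydrocortisone
testosterone	D04.210.500.054.844	Testosterone
troponin	D12.776.210.500.910	Troponin
natriuretic peptide	D12.644.548.691	Natriuretic Peptides
antibody titer	D12.776.124.486.485	Antibodies
viral load	E05.200.570.900	Viral Load
blood pressure	E01.370.600.875.249	Blood Pressure Determination
systolic blood pressure	E01.370.600.875.249	Blood Pressure Determination
bone mineral density	E01.370.350.700.055	Bone Density
cortical thickness	E01.370.376.537.250	Brain Cortical Thickness
forced expiratory volume	E01.370.386.700.485	Forced Expiratory Volume
fev1	E01.370.386.700.485	Forced Expiratory Volume
body mass index	E05.041.124	Body Mass Index
electrocardiogram	E01.370.370.380	Electrocardiography
magnetic resonance imaging	E01.370.350.825.500	Magnetic Resonance Imaging
biopsy	E01.370.225.500	Biopsy
survey	E05.318.308.980	Surveys and Questionnaires
surveys	E05.318.308.980	Surveys and Questionnaires
questionnaire	E05.318.308.980	Surveys and Questionnaires
questionnaires	E05.318.308.980	Surveys and Questionnaires
health survey	E05.318.308.980.438	Health Surveys
quality of life	E05.318.308.980.438.475	Quality of Life
infection	C01	Infections
infections	C01	Infections
influenza	C01.748.310	Influenza, Human
pneumonia	C01.748.610	Pneumonia
sepsis	C01.757	Sepsis
urinary tract infection	C01.915	Urinary Tract Infections
tuberculosis	C01.150.252.410.040.552.846	Tuberculosis
hepatitis	C01.925.440	Hepatitis, Viral, Human
neoplasm	C04	Neoplasms
cancer	C04	Neoplasms
carcinoma	C04.557.470	Carcinoma
lymphoma	C04.557.386	Lymphoma
rheumatoid arthritis	C05.550.114.154	Arthritis, Rheumatoid
osteoporosis	C05.116.198.579	Osteoporosis
osteoarthritis	C05.550.114.606	Osteoarthritis
crohn disease	C06.405.469.432.500	Crohn Disease
ulcerative colitis	C06.405.205.731.500	Colitis, Ulcerative
periodontitis	C07.465.714.533	Periodontitis
asthma	C08.127.108	Asthma
copd	C08.381.495.389	Pulmonary Disease, Chronic Obstructive
chronic obstructive pulmonary disease	C08.381.495.389	Pulmonary Disease, Chronic Obstructive
otitis media	C09.218.705	Otitis Media
migraine	C10.228.140.546.399.750	Migraine Disorders
epilepsy	C10.228.140.490	Epilepsy
multiple sclerosis	C10.114.375.500	Multiple Sclerosis
parkinson disease	C10.228.662.600.400	Parkinson Disease
alzheimer disease	C10.228.140.380.100	Alzheimer Disease
glaucoma	C11.525.381	Glaucoma
macular degeneration	C11.768.585.439	Macular Degeneration
kidney disease	C12.777.419	Kidney Diseases
chronic kidney disease	C12.777.419.780.750	Renal Insufficiency, Chronic
endometriosis	C13.351.500.056.630.705	Endometriosis
hypertension	C14.907.489	Hypertension
heart failure	C14.280.434	Heart Failure
myocardial infarction	C14.280.647.500	Myocardial Infarction
atrial fibrillation	C14.280.067.198	Atrial Fibrillation
stroke	C14.907.253.855	Stroke
anemia	C15.378.071	Anemia
cystic fibrosis	C16.320.190	Cystic Fibrosis
psoriasis	C17.800.859.675	Psoriasis
atopic dermatitis	C17.800.174.193	Dermatitis, Atopic
diabetes	C18.452.394.750	Diabetes Mellitus
diabetes mellitus	C18.452.394.750	Diabetes Mellitus
type 2 diabetes	C18.452.394.750.149	Diabetes Mellitus, Type 2
obesity	C18.654.726.500	Obesity
hypercholesterolemia	C18.452.584.500.500.396	Hypercholesterolemia
hypothyroidism	C19.874.482	Hypothyroidism
lupus	C20.111.590	Lupus Erythematosus, Systemic
allergy	C20.543	Hypersensitivity
pain	C23.888.592.612	Pain
fever	C23.888.119.344	Fever
fatigue	C23.888.369	Fatigue
chemotherapy-induced nausea	C25.100.468	Chemically-Induced Disorders
wound	C26.986	Wounds and Injuries
major depressive disorder	F03.600.300.375	Depressive Disorder, Major
depression	F03.600.300	Depressive Disorder
schizophrenia	F03.700.750	Schizophrenia
anxiety disorder	F03.080	Anxiety Disorders
bipolar disorder	F03.600.150.150	Bipolar Disorder
insomnia	F03.870.400	Sleep Initiation and Maintenance Disorders
imipenem	D02.065.589.099.750.511	Imipenem
cilastatin	D12.125.072.401	Cilastatin
paricalcitol	D04.210.500.247.808.197	Paricalcitol
ibuprofen	D02.241.223.701.430	Ibuprofen
oseltamivir	D02.241.081.038.687	Oseltamivir
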