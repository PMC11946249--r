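pt,soc
nausea,gastrointestinal disorders
vomiting,gastrointestinal disorders
diarrhea,gastrointestinal disorders
constipation,gastrointestinal disorders
decreased appetite,gastrointestinal disorders
dysphagia,gastrointestinal disorders
oesophagitis,gastrointestinal disorders
diverticulitis,gastrointestinal disorders
alanine aminotransferase increased,hepatobiliary disorders
aspartate aminotransferase increased,hepatobiliary disorders
transaminases increased,hepatobiliary disorders
hepatic enzyme increased,hepatobiliary disorders
hepatic enzyme abnormal,hepatobiliary disorders
hepatic function abnormal,hepatobiliary disorders
liver function test abnormal,hepatobiliary disorders
liver function test increased,hepatobiliary disorders
blood bilirubin increased,hepatobiliary disorders
bilirubin conjugated increased,hepatobiliary disorders
blood alkaline phosphatase increased,hepatobiliary disorders
gamma-glutamyltransferase increased,hepatobiliary disorders
hyperbilirubinaemia,hepatobiliary disorders
hyperbilirubinemia,hepatobiliary disorders
hepatotoxicity,hepatobiliary disorders
liver injury,hepatobiliary disorders
drug-induced liver injury,hepatobiliary disorders
hepatocellular injury,hepatobiliary disorders
cholestatic liver injury,hepatobiliary disorders
mixed liver injury,hepatobiliary disorders
liver disorder,hepatobiliary disorders
hepatic failure,hepatobiliary disorders
acute hepatic failure,hepatobiliary disorders
hepatic failure fatal,hepatobiliary disorders
hepatitis,hepatobiliary disorders
hepatitis acute,hepatobiliary disorders
hepatitis fulminant,hepatobiliary disorders
hepatitis toxic,hepatobiliary disorders
hepatitis cholestatic,hepatobiliary disorders
autoimmune hepatitis,hepatobiliary disorders
jaundice,hepatobiliary disorders
jaundice cholestatic,hepatobiliary disorders
ocular icterus,hepatobiliary disorders
cholestasis,hepatobiliary disorders
hepatic necrosis,hepatobiliary disorders
hepatic steatosis,hepatobiliary disorders
hepatic cirrhosis,hepatobiliary disorders
hepatomegaly,hepatobiliary disorders
hepatic encephalopathy,hepatobiliary disorders
hepatorenal syndrome,hepatobiliary disorders
DILI,hepatobiliary disorders
photopsia,eye disorders
visual impairment,eye disorders
vitreous floaters,eye disorders
diplopia,eye disorders
hypercholesterolemia,metabolism and nutrition disorders
blood triglycerides increased,metabolism and nutrition disorders
hyperglycemia,metabolism and nutrition disorders
hypokalemia,metabolism and nutrition disorders
hyperlipidemia,metabolism and nutrition disorders
hypertriglyceridemia,metabolism and nutrition disorders
dyslipidemia,metabolism and nutrition disorders
oedema peripheral,general disorders and administration site conditions
oedema,general disorders and administration site conditions
fatigue,general disorders and administration site conditions
pyrexia,general disorders and administration site conditions
death,general disorders and administration site conditions
sudden death,general disorders and administration site conditions
fluid retention,general disorders and administration site conditions
pleural effusion,"respiratory, thoracic and mediastinal disorders"
interstitial lung disease,"respiratory, thoracic and mediastinal disorders"
pneumonitis,"respiratory, thoracic and mediastinal disorders"
dyspnoea,"respiratory, thoracic and mediastinal disorders"
pulmonary embolism,"respiratory, thoracic and mediastinal disorders"
pulmonary oedema,"respiratory, thoracic and mediastinal disorders"
hemoptysis,"respiratory, thoracic and mediastinal disorders"
hypoxia,"respiratory, thoracic and mediastinal disorders"
respiratory failure,"respiratory, thoracic and mediastinal disorders"
pericardial effusion,cardiac disorders
bradycardia,cardiac disorders
cardiac failure,cardiac disorders
electrocardiogram qt prolonged,cardiac disorders
headache,nervous system disorders
dizziness,nervous system disorders
hallucination,psychiatric disorders
cognitive disorder,psychiatric disorders
rash,skin and subcutaneous tissue disorders
pruritus,skin and subcutaneous tissue disorders
photosensitivity reaction,skin and subcutaneous tissue disorders
anaemia,blood and lymphatic system disorders
hemolytic anemia,blood and lymphatic system disorders
hemolysis,blood and lymphatic system disorders
hemoglobin decreased,blood and lymphatic system disorders
renal impairment,renal and urinary disorders
blood creatinine increased,renal and urinary disorders
covid-19,infections and infestations
covid-19 pneumonia,infections and infestations
pneumonia bacterial,infections and infestations
metastases to central nervous system,"neoplasms benign, malignant and unspecified (incl cysts and polyps)"
metastases to liver,"neoplasms benign, malignant and unspecified (incl cysts and polyps)"
metastases to bone,"neoplasms benign, malignant and unspecified (incl cysts and polyps)"
malignant neoplasm progression,"neoplasms benign, malignant and unspecified (incl cysts and polyps)"
myalgia,musculoskeletal and connective tissue disorders
blood creatine phosphokinase increased,musculoskeletal and connective tissue disorders
weight increased,investigations
blood cholesterol increased,investigations
c-reactive protein increased,investigations
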