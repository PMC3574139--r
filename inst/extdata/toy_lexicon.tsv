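pain	sosy
cough	sosy
coughing	sosy
breathless	sosy
chest pain	sosy
painful	sosy
shortness of breath	sosy
coughing up blood	sosy
short of breath	sosy
wheezing	sosy
nausea	sosy
sore	sosy
nipple discharge	sosy
breast pain	sosy
itching	sosy
itchy	sosy
tingling	sosy
hot flashes	sosy
tired	sosy
thirsty	sosy
fatigue	sosy
frequent urination	sosy
hungry	sosy
dizzy	sosy
dizziness	sosy
headache	sosy
fever	sosy
vomiting	sosy
swelling	sosy
numbness	sosy
blurred vision	sosy
weight loss	sosy
night sweats	sosy
pneumonia	dsyn
infection	dsyn|patf
tuberculosis	dsyn
bronchitis	dsyn
asthma	dsyn
copd	dsyn
pleural effusion	dsyn
emphysema	dsyn
atelectasis	dsyn
collapsed lung	acab
lymph edema	dsyn
rash	sosy
fibrocystic breast	dsyn
fibrocystic disease	dsyn
fibrocystic breast disease	dsyn
mastitis	dsyn
idc	neop
eczema	dsyn
complex cyst	anab
complex cysts	anab
paget's disease	dsyn
neuropathy	dsyn
hypoglycaemia	dsyn|patf
hypoglycemia	dsyn|patf
low blood sugar	patf
dka	dsyn|patf
pcos	dsyn
coma	dsyn|patf
kidney disease	dsyn
obesity	dsyn
diabetic neuropathy	dsyn
diabetes	dsyn
anemia	dsyn
depression	mobd
anxiety	mobd
cat scan	diap
biopsy	diap
x-ray	diap
pet scan	diap
chest x-ray	diap
scan	diap
mri	diap
bronchoscopy	diap
imaging	diap
biopsy needle	diap
mammogram	diap
ultrasound	diap
bi-rads	diap
core biopsy	diap
screening	diap
colonoscopy	diap
endoscopy	diap
blood test	lbpr
fasting test	lbpr
glucose test	lbpr
fasting blood sugar	lbpr
hemoglobin a1c test	lbpr
hemoglobin a1c	lbpr
glucose tolerance test	lbpr
gtts	lbpr
blood work	lbpr
blood count	lbpr
urine test	lbpr
cholesterol test	lbpr
chemo	topp
radiation	topp
chemotherapy	topp
lobectomy	topp
operation	topp
therapy	topp
surgery	topp
removal	topp
radiation therapy	topp
wedge resection	topp
mastectomy	topp
lumpectomy	topp
implant	topp
radiotherapy	topp
surgical	topp
infusion	topp
injection	topp
transplant	topp
dialysis	topp
amputation	topp
insulin injection	topp
physical therapy	topp
vaccination	topp
silicas	phsu
tarceva	phsu|orch
morphine	phsu|orch
chantix	phsu
carboplatin	phsu|orch
coumadin	phsu|orch
alimta	phsu
advil	phsu
taxol	phsu|orch
dilaudid	phsu
tamoxifen	phsu|orch
arimidex	phsu
femara	phsu
taxotere	phsu
effexor	phsu
raloxifene	phsu|orch
valium	phsu
docetaxel	phsu|orch
insulin	phsu|horm|aapp
lantus	phsu
metformin	phsu|orch
januvia	phsu
glucophage	phsu
actos	phsu
marihuana	phsu
avandia	phsu
glipizide	phsu|orch
amaryl	phsu
aspirin	phsu|orch
ibuprofen	phsu|orch
tylenol	phsu
prednisone	phsu|orch
antibiotics	phsu
estrogen	horm|phsu
progesterone	horm|phsu
cortisol	horm
thyroid hormone	horm
antibody	imft|aapp
vaccine	imft|phsu
interferon	imft|aapp
glucose	orch|aapp
hemoglobin	aapp
lung	bpoc
breast	bpoc
chest	blor
abdomen	blor
armpit	blor
pancreas	bpoc
kidney	bpoc
liver	bpoc
lymph node	bpoc
thyroid	bpoc
bronchus	bpoc
nipple	bpoc
immune system	bdsy
respiratory system	bdsy
nervous system	bdsy
oncology	bmod
radiology	bmod
endocrinology	bmod
lung cancer	neop
breast cancer	neop
cancer	neop
tumor	neop
tumour	neop
carcinoma	neop
metastasis	neop
adenocarcinoma	neop
cyst	anab
nodule	anab
lesion	anab
fracture	inpo
burn	inpo
overdose	inpo
scar	acab
hernia	acab
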