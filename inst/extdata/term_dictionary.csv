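variant,token
diabetes,diabetes
diabetes mellitus,diabetes
diabetes mellitus type 2,diabetes
type 2 diabetes,diabetes
type 2 diabetes mellitus,diabetes
type ii diabetes mellitus,diabetes
type ii diabetes,diabetes
type 1 diabetes,diabetes
type i diabetes mellitus,diabetes
dm2,diabetes
dm 2,diabetes
dm ii,diabetes
niddm,diabetes
iddm,diabetes
hypertension,hypertension
essential hypertension,hypertension
high blood pressure,hypertension
htn,hypertension
hypothyroidism,hypothyroidism
hypothyroid,hypothyroidism
underactive thyroid,hypothyroidism
low thyroid,hypothyroidism
primary hypothyroidism,hypothyroidism
asthma,asthma
asthmatic,asthma
reactive airway disease,asthma
obesity,obesity
obese,obesity
morbid obesity,obesity
urinary tract infection,urinary_tract_infection
uti,urinary_tract_infection
cystitis,urinary_tract_infection
acute cystitis,urinary_tract_infection
bladder infection,urinary_tract_infection
recurrent uti,urinary_tract_infection
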