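synonym,pt_code,pt_name,hlt_code,hlgt_code,soc_code
spinal fracture,PT0001,Spinal fracture,HLT001,HLG001,SOC01
spine fracture,PT0001,Spinal fracture,HLT001,HLG001,SOC01
fractured spine,PT0001,Spinal fracture,HLT001,HLG001,SOC01
broken vertebra,PT0001,Spinal fracture,HLT001,HLG001,SOC01
vertebral fracture,PT0001,Spinal fracture,HLT001,HLG001,SOC01
thoracic vertebral fracture,PT0002,Thoracic vertebral fracture,HLT001,HLG001,SOC01
fractured thoracic vertebra,PT0002,Thoracic vertebral fracture,HLT001,HLG001,SOC01
lumbar vertebral fracture,PT0003,Lumbar vertebral fracture,HLT001,HLG001,SOC01
fractured lumbar vertebra,PT0003,Lumbar vertebral fracture,HLT001,HLG001,SOC01
cervical vertebral fracture,PT0004,Cervical vertebral fracture,HLT001,HLG001,SOC01
fractured neck vertebra,PT0004,Cervical vertebral fracture,HLT001,HLG001,SOC01
fracture,PT0005,Fracture,HLT001,HLG001,SOC01
broken bone,PT0005,Fracture,HLT001,HLG001,SOC01
hip fracture,PT0006,Hip fracture,HLT001,HLG001,SOC01
broken hip,PT0006,Hip fracture,HLT001,HLG001,SOC01
osteoporosis,PT0007,Osteoporosis,HLT002,HLG001,SOC01
brittle bones,PT0007,Osteoporosis,HLT002,HLG001,SOC01
bone thinning,PT0007,Osteoporosis,HLT002,HLG001,SOC01
osteopenia,PT0008,Osteopenia,HLT002,HLG001,SOC01
low bone density,PT0008,Osteopenia,HLT002,HLG001,SOC01
osteonecrosis of the jaw,PT0009,Osteonecrosis of jaw,HLT003,HLG001,SOC01
jaw necrosis,PT0009,Osteonecrosis of jaw,HLT003,HLG001,SOC01
bone pain,PT0010,Bone pain,HLT003,HLG001,SOC01
aching bones,PT0010,Bone pain,HLT003,HLG001,SOC01
back pain,PT0011,Back pain,HLT003,HLG001,SOC01
sore back,PT0011,Back pain,HLT003,HLG001,SOC01
muscle cramps,PT0012,Muscle spasms,HLT004,HLG001,SOC01
muscle spasms,PT0012,Muscle spasms,HLT004,HLG001,SOC01
stevens-johnson syndrome,PT0013,Stevens-Johnson syndrome,HLT005,HLG002,SOC02
sjs rash,PT0013,Stevens-Johnson syndrome,HLT005,HLG002,SOC02
toxic epidermal necrolysis,PT0014,Toxic epidermal necrolysis,HLT005,HLG002,SOC02
skin sloughing,PT0014,Toxic epidermal necrolysis,HLT005,HLG002,SOC02
erythema multiforme,PT0015,Erythema multiforme,HLT005,HLG002,SOC02
target lesions,PT0015,Erythema multiforme,HLT005,HLG002,SOC02
dermatitis exfoliative,PT0016,Dermatitis exfoliative,HLT005,HLG002,SOC02
exfoliative dermatitis,PT0016,Dermatitis exfoliative,HLT005,HLG002,SOC02
peeling skin,PT0016,Dermatitis exfoliative,HLT005,HLG002,SOC02
pemphigoid,PT0017,Pemphigoid,HLT005,HLG002,SOC02
blistering rash,PT0017,Pemphigoid,HLT005,HLG002,SOC02
skin rash,PT0018,Rash,HLT006,HLG002,SOC02
itchy rash,PT0018,Rash,HLT006,HLG002,SOC02
hives,PT0019,Urticaria,HLT006,HLG002,SOC02
urticaria,PT0019,Urticaria,HLT006,HLG002,SOC02
itching,PT0020,Pruritus,HLT006,HLG002,SOC02
pruritus,PT0020,Pruritus,HLT006,HLG002,SOC02
nausea,PT0021,Nausea,HLT007,HLG003,SOC03
queasy stomach,PT0021,Nausea,HLT007,HLG003,SOC03
vomiting,PT0022,Vomiting,HLT007,HLG003,SOC03
throwing up,PT0022,Vomiting,HLT007,HLG003,SOC03
diarrhoea,PT0023,Diarrhoea,HLT008,HLG003,SOC03
diarrhea,PT0023,Diarrhoea,HLT008,HLG003,SOC03
constipation,PT0024,Constipation,HLT008,HLG003,SOC03
severe fatigue,PT0025,Fatigue,HLT009,HLG004,SOC04
exhausted all the time,PT0025,Fatigue,HLT009,HLG004,SOC04
fatigue,PT0025,Fatigue,HLT009,HLG004,SOC04
fever,PT0026,Pyrexia,HLT009,HLG004,SOC04
high temperature,PT0026,Pyrexia,HLT009,HLG004,SOC04
chills,PT0027,Chills,HLT009,HLG004,SOC04
low calcium,PT0028,Hypocalcaemia,HLT010,HLG004,SOC04
hypocalcaemia,PT0028,Hypocalcaemia,HLT010,HLG004,SOC04
calcium dropped,PT0028,Hypocalcaemia,HLT010,HLG004,SOC04
headache,PT0029,Headache,HLT011,HLG005,SOC05
migraine,PT0030,Migraine,HLT011,HLG005,SOC05
dizziness,PT0031,Dizziness,HLT011,HLG005,SOC05
dizzy spells,PT0031,Dizziness,HLT011,HLG005,SOC05
numb fingers,PT0032,Paraesthesia,HLT012,HLG005,SOC05
tingling hands,PT0032,Paraesthesia,HLT012,HLG005,SOC05
joint pain,PT0033,Arthralgia,HLT004,HLG001,SOC01
aching joints,PT0033,Arthralgia,HLT004,HLG001,SOC01
shortness of breath,PT0034,Dyspnoea,HLT013,HLG006,SOC06
breathless,PT0034,Dyspnoea,HLT013,HLG006,SOC06
pneumonitis,PT0035,Pneumonitis,HLT013,HLG006,SOC06
lung inflammation,PT0035,Pneumonitis,HLT013,HLG006,SOC06
colitis,PT0036,Colitis,HLT008,HLG003,SOC03
inflamed colon,PT0036,Colitis,HLT008,HLG003,SOC03
thyroid underactive,PT0037,Hypothyroidism,HLT010,HLG004,SOC04
hypothyroidism,PT0037,Hypothyroidism,HLT010,HLG004,SOC04
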