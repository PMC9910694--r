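- dimension: A
  layer: major
  parent_path: ''
  label: cardiovascular disease
  code: '01'
  provenance: stated
- dimension: A
  layer: major
  parent_path: ''
  label: digestive system disease
  code: '02'
  provenance: stated
- dimension: A
  layer: major
  parent_path: ''
  label: respiratory system disease
  code: '03'
  provenance: stated
- dimension: A
  layer: major
  parent_path: ''
  label: urinary system disease
  code: '04'
  provenance: stated
- dimension: A
  layer: major
  parent_path: ''
  label: reproductive system disease
  code: '05'
  provenance: stated
- dimension: A
  layer: major
  parent_path: ''
  label: endocrine disease
  code: '06'
  provenance: stated
- dimension: A
  layer: major
  parent_path: ''
  label: ophthalmology and otolaryngology disease
  code: '07'
  provenance: stated
- dimension: A
  layer: major
  parent_path: ''
  label: oral disease
  code: 08
  provenance: stated
- dimension: A
  layer: major
  parent_path: ''
  label: bone disease
  code: 09
  provenance: stated
- dimension: A
  layer: major
  parent_path: ''
  label: skin disease
  code: '10'
  provenance: stated
- dimension: A
  layer: major
  parent_path: ''
  label: nervous system disease
  code: '11'
  provenance: stated
- dimension: A
  layer: major
  parent_path: ''
  label: blood system disease
  code: '12'
  provenance: stated
- dimension: A
  layer: major
  parent_path: ''
  label: infectious disease
  code: '13'
  provenance: stated
- dimension: A
  layer: major
  parent_path: ''
  label: tumor
  code: '14'
  provenance: stated
- dimension: A
  layer: major
  parent_path: ''
  label: TCM viscera dialectics
  code: '15'
  provenance: stated
- dimension: A
  layer: major
  parent_path: ''
  label: other diseases
  code: '16'
  provenance: stated
- dimension: A
  layer: intermediate
  parent_path: cardiovascular disease
  label: myocarditis
  code: '01'
  provenance: stated
- dimension: A
  layer: intermediate
  parent_path: cardiovascular disease
  label: pericarditis
  code: '02'
  provenance: stated
- dimension: A
  layer: intermediate
  parent_path: cardiovascular disease
  label: myocardial infarction
  code: '03'
  provenance: stated
- dimension: A
  layer: intermediate
  parent_path: cardiovascular disease
  label: arrhythmia
  code: '04'
  provenance: stated
- dimension: A
  layer: intermediate
  parent_path: cardiovascular disease
  label: myocardial ischemia
  code: '05'
  provenance: stated
- dimension: A
  layer: intermediate
  parent_path: cardiovascular disease
  label: arterial thrombosis
  code: '06'
  provenance: stated
- dimension: A
  layer: intermediate
  parent_path: cardiovascular disease
  label: hypertension
  code: '07'
  provenance: stated
- dimension: A
  layer: intermediate
  parent_path: cardiovascular disease
  label: atherosclerosis
  code: 08
  provenance: stated
- dimension: A
  layer: intermediate
  parent_path: respiratory system disease
  label: SARS-CoV-2 infection
  code: '12'
  provenance: inferred
- dimension: B
  layer: major
  parent_path: ''
  label: laboratory animal
  code: '11'
  provenance: stated
- dimension: B
  layer: species
  parent_path: laboratory animal
  label: mouse
  code: '11'
  provenance: stated
- dimension: B
  layer: species
  parent_path: laboratory animal
  label: rat
  code: '13'
  provenance: stated
- dimension: B
  layer: species
  parent_path: laboratory animal
  label: guinea pig
  code: '15'
  provenance: stated
- dimension: B
  layer: species
  parent_path: laboratory animal
  label: rabbit
  code: '27'
  provenance: inferred
- dimension: B
  layer: strain
  parent_path: laboratory animal/mouse
  label: BALB/c
  code: '001'
  provenance: stated
- dimension: B
  layer: strain
  parent_path: laboratory animal/mouse
  label: KM
  code: '002'
  provenance: stated
- dimension: B
  layer: strain
  parent_path: laboratory animal/mouse
  label: C57
  code: '003'
  provenance: stated
- dimension: B
  layer: strain
  parent_path: laboratory animal/mouse
  label: ICR-Tg(hACE2)
  code: '017'
  provenance: inferred
- dimension: B
  layer: strain
  parent_path: laboratory animal/rat
  label: SD
  code: '001'
  provenance: stated
- dimension: B
  layer: strain
  parent_path: laboratory animal/rat
  label: Wistar
  code: '002'
  provenance: stated
- dimension: B
  layer: strain
  parent_path: laboratory animal/rabbit
  label: New Zealand
  code: '001'
  provenance: stated
- dimension: C
  layer: category
  parent_path: ''
  label: spontaneous
  code: '01'
  provenance: stated
- dimension: C
  layer: category
  parent_path: ''
  label: induced
  code: '02'
  provenance: stated
- dimension: C
  layer: category
  parent_path: ''
  label: genetic engineering
  code: '03'
  provenance: stated
- dimension: D
  layer: cooperation
  parent_path: ''
  label: independence
  code: '1'
  provenance: stated
- dimension: D
  layer: cooperation
  parent_path: ''
  label: cooperation
  code: '2'
  provenance: stated
- dimension: D
  layer: cooperation
  parent_path: ''
  label: outsourcing
  code: '3'
  provenance: stated
- dimension: D
  layer: sharing
  parent_path: ''
  label: paid
  code: '1'
  provenance: stated
- dimension: D
  layer: sharing
  parent_path: ''
  label: free
  code: '2'
  provenance: stated
- dimension: D
  layer: preservation
  parent_path: ''
  label: live
  code: '1'
  provenance: stated
- dimension: D
  layer: preservation
  parent_path: ''
  label: frozen
  code: '2'
  provenance: stated
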