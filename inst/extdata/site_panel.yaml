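# Default cancer-site panel: 14 reporting groups + all-sites aggregate.
# parity_rr is the relative risk of the cancer in parous vs nulliparous
# women; 1.0 means no parity adjustment. Breast and cervical parity RRs are
# known to exist but no authoritative default is shipped (users supply their
# own values); the site-specific ovarian entry carries the established 0.8.
sites:
  - name: Brain, meninges and CNS
    icd10: C70-72, D32-33, D42-43
    parity_rr: 1.0
  - name: Breast
    icd10: C50
    parity_rr: 1.0   # placeholder: parity-breast association established, value user-supplied
  - name: Colon and rectum
    icd10: C18-20
    parity_rr: 1.0
  - name: Female genital organs
    icd10: C51-58
    parity_rr: 1.0   # cervical parity RR applies only to a cervix-specific surface
  - name: Gallbladder, bile ducts
    icd10: C23-24
    parity_rr: 1.0
  - name: Haematological
    icd10: C81-96, D45-47, D76
    parity_rr: 1.0
  - name: Kidney
    icd10: C64
    parity_rr: 1.0
  - name: Liver
    icd10: C22
    parity_rr: 1.0
  - name: Lung, trachea
    icd10: C33-34
    parity_rr: 1.0
  - name: Melanoma of the skin
    icd10: C43
    parity_rr: 1.0
  - name: Pancreas
    icd10: C25
    parity_rr: 1.0
  - name: Stomach
    icd10: C16
    parity_rr: 1.0
  - name: Thyroid gland
    icd10: C73
    parity_rr: 1.0
  - name: Other
    icd10: C00-15, C17, C21, C26, C30-32, C37-41, C45-49, C65-69, C74-80, D09.0-1, D41.1-9
    parity_rr: 1.0
  - name: All sites
    icd10: C00-96, D09.0-1, D32-33, D41-43, D45-47, D76, excluding C44
    parity_rr: 1.0
  - name: Ovary
    icd10: C56
    parity_rr: 0.8   # parous vs nulliparous; applies to ovary-specific surfaces only
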