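# Working registry specification for the synthetic-CDW pipeline: a compact
# schema exercising every category, transform kind and quality rule. Element
# ids are table-prefixed because ids are unique across the whole schema.
version: "demo-1"
tables:
  - table: person
    category: Person
    subcategory: Person
    primary_key: [person_id]
    elements:
      - {id: person_id, name: Patient identifier, type: code, not_null: true}
      - {id: sex, name: Sex, type: code, not_null: true}
      - {id: birth_date, name: Date of birth, type: date, not_null: true}
      - {id: death_date, name: Date of death, type: date}
  - table: diagnosis_all
    category: Diagnosis
    subcategory: ALL
    primary_key: [dx_id]
    foreign_keys:
      - {element: dx_person_id, ref_table: person, ref_element: person_id}
    elements:
      - {id: dx_id, name: Diagnosis record id, type: code, not_null: true}
      - {id: dx_person_id, name: Patient identifier, type: code, not_null: true}
      - {id: icd10_code, name: ICD-10 code, type: code, not_null: true}
      - {id: diag_date, name: First ALL diagnosis date, type: date, not_null: true}
      - {id: wbc_at_dx, name: WBC at diagnosis (10^9/L), type: decimal}
  - table: lab_peripheral_blood
    category: Laboratory
    subcategory: Peripheral Blood
    primary_key: [pb_lab_id]
    foreign_keys:
      - {element: pb_person_id, ref_table: person, ref_element: person_id}
      - {element: pb_visit_id, ref_table: visit, ref_element: visit_id}
    elements:
      - {id: pb_lab_id, name: Lab record id, type: code, not_null: true}
      - {id: pb_person_id, name: Patient identifier, type: code, not_null: true}
      - {id: pb_visit_id, name: Visit reference, type: code}
      - {id: pb_test_date, name: Test date, type: date, not_null: true}
      - {id: pb_wbc, name: White blood cell count, type: decimal,
         domain: {min: 0, max: 1000}}
  - table: lab_bone_marrow
    category: Laboratory
    subcategory: Bone Marrow
    primary_key: [bm_lab_id]
    foreign_keys:
      - {element: bm_person_id, ref_table: person, ref_element: person_id}
      - {element: bm_visit_id, ref_table: visit, ref_element: visit_id}
    elements:
      - {id: bm_lab_id, name: Lab record id, type: code, not_null: true}
      - {id: bm_person_id, name: Patient identifier, type: code, not_null: true}
      - {id: bm_visit_id, name: Visit reference, type: code}
      - {id: bm_test_date, name: Test date, type: date, not_null: true}
      - {id: bm_blast_pct, name: Marrow blast percentage, type: decimal,
         domain: {min: 0, max: 100}}
  - table: lab_chromosome
    category: Laboratory
    subcategory: Chromosome
    primary_key: [chr_lab_id]
    foreign_keys:
      - {element: chr_person_id, ref_table: person, ref_element: person_id}
    elements:
      - {id: chr_lab_id, name: Lab record id, type: code, not_null: true}
      - {id: chr_person_id, name: Patient identifier, type: code, not_null: true}
      - {id: chr_test_date, name: Test date, type: date, not_null: true}
      - {id: chr_count, name: Modal chromosome count, type: integer,
         domain: {min: 20, max: 100}}
      - {id: chr_ploidy, name: Ploidy class, type: code}
  - table: lab_fish
    category: Laboratory
    subcategory: FISH
    primary_key: [fish_lab_id]
    foreign_keys:
      - {element: fish_person_id, ref_table: person, ref_element: person_id}
    elements:
      - {id: fish_lab_id, name: Lab record id, type: code, not_null: true}
      - {id: fish_person_id, name: Patient identifier, type: code, not_null: true}
      - {id: fish_test_date, name: Test date, type: date, not_null: true}
      - {id: fish_probe, name: Probe symbol, type: code}
      - {id: fish_copy_number, name: Probe copy number, type: integer}
      - {id: fish_call, name: Abnormality call, type: code}
  - table: lab_flow
    category: Laboratory
    subcategory: Flow Cytometry
    primary_key: [flow_lab_id]
    foreign_keys:
      - {element: flow_person_id, ref_table: person, ref_element: person_id}
    elements:
      - {id: flow_lab_id, name: Lab record id, type: code, not_null: true}
      - {id: flow_person_id, name: Patient identifier, type: code, not_null: true}
      - {id: flow_test_date, name: Test date, type: date, not_null: true}
      - {id: flow_lineage, name: Immunophenotype lineage, type: code}
  - table: drug
    category: Drug
    subcategory: Chemotherapy
    primary_key: [rx_id]
    foreign_keys:
      - {element: rx_person_id, ref_table: person, ref_element: person_id}
      - {element: rx_visit_id, ref_table: visit, ref_element: visit_id}
    elements:
      - {id: rx_id, name: Prescription record id, type: code, not_null: true}
      - {id: rx_person_id, name: Patient identifier, type: code, not_null: true}
      - {id: rx_visit_id, name: Visit reference, type: code}
      - {id: drug_code, name: Drug code, type: code, not_null: true}
      - {id: drug_name, name: Drug name, type: text}
      - {id: rx_date, name: Prescription date, type: date, not_null: true}
  - table: surgery
    category: Surgery
    subcategory: ALL Surgery
    primary_key: [proc_id]
    foreign_keys:
      - {element: proc_person_id, ref_table: person, ref_element: person_id}
    elements:
      - {id: proc_id, name: Procedure record id, type: code, not_null: true}
      - {id: proc_person_id, name: Patient identifier, type: code, not_null: true}
      - {id: proc_name, name: Procedure name, type: text}
      - {id: proc_date, name: Procedure date, type: date, not_null: true}
  - table: hsct
    category: HSCT
    subcategory: HSCT
    primary_key: [hsct_id]
    foreign_keys:
      - {element: hsct_person_id, ref_table: person, ref_element: person_id}
    elements:
      - {id: hsct_id, name: Transplant record id, type: code, not_null: true}
      - {id: hsct_person_id, name: Patient identifier, type: code, not_null: true}
      - {id: hsct_date, name: Transplant date, type: date, not_null: true}
      - {id: donor_type, name: Donor type, type: code}
  - table: visit
    category: Visit
    subcategory: Visit
    primary_key: [visit_id]
    foreign_keys:
      - {element: visit_person_id, ref_table: person, ref_element: person_id}
    elements:
      - {id: visit_id, name: Visit record id, type: code, not_null: true}
      - {id: visit_person_id, name: Patient identifier, type: code, not_null: true}
      - {id: visit_date, name: Visit date, type: date, not_null: true}
      - {id: visit_type, name: Visit type (IN/OUT), type: code, not_null: true}
      - {id: dept_code, name: Department code, type: integer,
         domain: {min: 1, max: 26}}
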