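# Build-mapping configuration for the synthetic-CDW dialects. One block per
# registry table: the source relation, an optional row filter/reduction and
# one entry per element. NLP entries parse the narrative result column and
# fall back to the structured column for rows stored tabularly.
mappings:
  - table: person
    source: patients
    row_key: patient_id
    elements:
      - {element: person_id, kind: direct, column: patient_id}
      - {element: sex, kind: direct, column: sex, transform: sex_code}
      - {element: birth_date, kind: direct, column: birth_date}
      - {element: death_date, kind: direct, column: death_date}
  - table: diagnosis_all
    source: diagnoses
    filter: {column: icd10, equals: C91.0}
    reduce: first_by_date
    reduce_date: diag_date
    row_key: dx_id
    elements:
      - {element: dx_id, kind: direct, column: dx_id}
      - {element: dx_person_id, kind: direct, column: patient_id}
      - {element: icd10_code, kind: direct, column: icd10}
      - {element: diag_date, kind: direct, column: diag_date}
      - {element: wbc_at_dx, kind: multivariate, transform: nearest_lab_value,
         params: {lab_type: WBC, anchor_column: diag_date, window_days: 7}}
  - table: lab_peripheral_blood
    source: labs
    filter: {column: lab_type, equals: WBC}
    row_key: lab_id
    elements:
      - {element: pb_lab_id, kind: direct, column: lab_id}
      - {element: pb_person_id, kind: direct, column: patient_id}
      - {element: pb_visit_id, kind: direct, column: visit_id}
      - {element: pb_test_date, kind: direct, column: lab_date}
      - {element: pb_wbc, kind: direct, column: value_num}
  - table: lab_bone_marrow
    source: labs
    filter: {column: lab_type, equals: BLAST}
    row_key: lab_id
    elements:
      - {element: bm_lab_id, kind: direct, column: lab_id}
      - {element: bm_person_id, kind: direct, column: patient_id}
      - {element: bm_visit_id, kind: direct, column: visit_id}
      - {element: bm_test_date, kind: direct, column: lab_date}
      - {element: bm_blast_pct, kind: direct, column: value_num}
  - table: lab_chromosome
    source: labs
    filter: {column: lab_type, equals: KARYOTYPE}
    row_key: lab_id
    elements:
      - {element: chr_lab_id, kind: direct, column: lab_id}
      - {element: chr_person_id, kind: direct, column: patient_id}
      - {element: chr_test_date, kind: direct, column: lab_date}
      - {element: chr_count, kind: nlp, parser: karyotype, column: value_text,
         fallback_column: value_num, field: chromosome_count}
      - {element: chr_ploidy, kind: nlp, parser: karyotype, column: value_text,
         fallback_column: value_num, field: ploidy_class}
  - table: lab_fish
    source: labs
    filter: {column: lab_type, equals: FISH}
    row_key: lab_id
    elements:
      - {element: fish_lab_id, kind: direct, column: lab_id}
      - {element: fish_person_id, kind: direct, column: patient_id}
      - {element: fish_test_date, kind: direct, column: lab_date}
      - {element: fish_probe, kind: nlp, parser: fish, column: value_text,
         fallback_column: probe_symbol, field: probe}
      - {element: fish_copy_number, kind: nlp, parser: fish, column: value_text,
         fallback_column: copy_number, field: copy_number}
      - {element: fish_call, kind: nlp, parser: fish, column: value_text,
         fallback_column: copy_number, field: call}
  - table: lab_flow
    source: labs
    filter: {column: lab_type, equals: FLOW}
    row_key: lab_id
    elements:
      - {element: flow_lab_id, kind: direct, column: lab_id}
      - {element: flow_person_id, kind: direct, column: patient_id}
      - {element: flow_test_date, kind: direct, column: lab_date}
      - {element: flow_lineage, kind: nlp, parser: flow, column: value_text,
         fallback_column: lineage, field: lineage}
  - table: drug
    source: drugs
    row_key: rx_id
    elements:
      - {element: rx_id, kind: direct, column: rx_id}
      - {element: rx_person_id, kind: direct, column: patient_id}
      - {element: rx_visit_id, kind: direct, column: visit_id}
      - {element: drug_code, kind: direct, column: drug_code}
      - {element: drug_name, kind: direct, column: drug_name}
      - {element: rx_date, kind: direct, column: rx_date}
  - table: surgery
    source: procedures
    row_key: proc_id
    elements:
      - {element: proc_id, kind: direct, column: proc_id}
      - {element: proc_person_id, kind: direct, column: patient_id}
      - {element: proc_name, kind: direct, column: proc_name}
      - {element: proc_date, kind: direct, column: proc_date}
  - table: hsct
    source: hsct
    row_key: hsct_id
    elements:
      - {element: hsct_id, kind: direct, column: hsct_id}
      - {element: hsct_person_id, kind: direct, column: patient_id}
      - {element: hsct_date, kind: direct, column: hsct_date}
      - {element: donor_type, kind: direct, column: donor_type}
  - table: visit
    source: visits
    row_key: visit_id
    elements:
      - {element: visit_id, kind: direct, column: visit_id}
      - {element: visit_person_id, kind: direct, column: patient_id}
      - {element: visit_date, kind: direct, column: visit_date}
      - {element: visit_type, kind: direct, column: visit_type}
      - {element: dept_code, kind: direct, column: dept_code}
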