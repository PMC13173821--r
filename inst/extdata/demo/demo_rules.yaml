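# Quality rule pack for the demo registry: every dimension/subdimension is
# covered, with the canonical worked rules (out-of-range department code,
# impossible calendar date, event after death, leucovorin without prior
# methotrexate, duplicate primary key, dangling foreign key). Business rules
# are flag-only by design: they need clinical interpretation.
rules:
  # completeness --------------------------------------------------------
  - {id: comp_person_sex, dimension: completeness, table: person,
     element: sex, check: not_null, remediation: mark_na}
  - {id: comp_visit_type, dimension: completeness, table: visit,
     element: visit_type, check: not_null, remediation: mark_na}
  - {id: comp_visit_date, dimension: completeness, table: visit,
     element: visit_date, check: not_null, remediation: mark_na}
  - {id: comp_diag_date, dimension: completeness, table: diagnosis_all,
     element: diag_date, check: not_null, remediation: mark_na}
  # validity / range ----------------------------------------------------
  - {id: val_dept_code, dimension: validity, subdimension: range,
     table: visit, element: dept_code, check: range, min: 1, max: 26,
     remediation: exclude_invalid}
  - {id: val_blast_pct, dimension: validity, subdimension: range,
     table: lab_bone_marrow, element: bm_blast_pct, check: range,
     min: 0, max: 100, remediation: exclude_invalid}
  - {id: val_wbc, dimension: validity, subdimension: range,
     table: lab_peripheral_blood, element: pb_wbc, check: range,
     min: 0, max: 1000, remediation: exclude_invalid}
  - {id: val_chr_count, dimension: validity, subdimension: range,
     table: lab_chromosome, element: chr_count, check: range,
     min: 20, max: 100, remediation: exclude_invalid}
  # validity / format ---------------------------------------------------
  - {id: fmt_visit_date, dimension: validity, subdimension: format,
     table: visit, element: visit_date, check: format_date,
     remediation: exclude_invalid}
  - {id: fmt_diag_date, dimension: validity, subdimension: format,
     table: diagnosis_all, element: diag_date, check: format_date,
     remediation: exclude_invalid}
  - {id: fmt_pb_date, dimension: validity, subdimension: format,
     table: lab_peripheral_blood, element: pb_test_date, check: format_date,
     remediation: exclude_invalid}
  # accuracy / timeline -------------------------------------------------
  - {id: tl_visit_death, dimension: accuracy, subdimension: timeline,
     table: visit, element: visit_date, check: not_after_death,
     person_column: visit_person_id, remediation: verify_date}
  - {id: tl_pb_death, dimension: accuracy, subdimension: timeline,
     table: lab_peripheral_blood, element: pb_test_date,
     check: not_after_death, person_column: pb_person_id,
     remediation: verify_date}
  - {id: tl_bm_death, dimension: accuracy, subdimension: timeline,
     table: lab_bone_marrow, element: bm_test_date, check: not_after_death,
     person_column: bm_person_id, remediation: verify_date}
  # accuracy / business rule -------------------------------------------
  - {id: br_leucovorin_mtx, dimension: accuracy, subdimension: business_rule,
     table: drug, check: drug_pair_within, trigger_code: LV,
     required_code: MTX, days: 7, code_column: drug_code,
     date_column: rx_date, person_column: rx_person_id,
     remediation: flag_only}
  # uniqueness ----------------------------------------------------------
  - {id: uq_person, dimension: uniqueness, table: person, check: unique_key,
     remediation: reload_dedupe}
  - {id: uq_visit, dimension: uniqueness, table: visit, check: unique_key,
     remediation: reload_dedupe}
  - {id: uq_drug, dimension: uniqueness, table: drug, check: unique_key,
     remediation: reload_dedupe}
  # consistency / relationship -----------------------------------------
  - {id: fk_visit_person, dimension: consistency, subdimension: relationship,
     table: visit, element: visit_person_id, check: fk_exists,
     ref_table: person, ref_element: person_id, remediation: reindex_fk}
  - {id: fk_pb_visit, dimension: consistency, subdimension: relationship,
     table: lab_peripheral_blood, element: pb_visit_id, check: fk_exists,
     ref_table: visit, ref_element: visit_id, remediation: reindex_fk}
  - {id: fk_bm_visit, dimension: consistency, subdimension: relationship,
     table: lab_bone_marrow, element: bm_visit_id, check: fk_exists,
     ref_table: visit, ref_element: visit_id, remediation: reindex_fk}
  - {id: fk_drug_visit, dimension: consistency, subdimension: relationship,
     table: drug, element: rx_visit_id, check: fk_exists,
     ref_table: visit, ref_element: visit_id, remediation: reindex_fk}
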