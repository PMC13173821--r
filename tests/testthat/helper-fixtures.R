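# Shared fixtures: packaged config paths and a hand-built micro-extract
# constructor for cohort boundary cases.

fixture <- function(...) system.file("extdata", ..., package = "allregistry")

published_schema <- function() load_schema(fixture("registry_schema.yaml"))

site_classifications <- function(site = c("site_a", "site_b")) {
  site <- match.arg(site)
  classify_elements(fixture(sprintf("mappings_%s.yaml", site)),
                    fixture(sprintf("inventory_%s.yaml", site)))
}

published_dq_counts <- function(site, phase) {
  df <- utils::read.csv(fixture("dq_counts.csv"), stringsAsFactors = FALSE)
  df[df$institution == site & df$phase == phase, , drop = FALSE]
}

# Minimal hand-constructed CDW extract. Supply data.frames for the relations
# under test; the rest default to empty but well-typed.
micro_extract <- function(patients, diagnoses,
                          labs = NULL, drugs = NULL, visits = NULL) {
  empty_labs <- data.frame(lab_id = character(0), patient_id = character(0),
                           visit_id = character(0), lab_type = character(0),
                           lab_date = character(0), value_num = character(0),
                           value_text = character(0),
                           is_narrative = character(0),
                           probe_symbol = character(0),
                           copy_number = character(0), lineage = character(0),
                           stringsAsFactors = FALSE)
  structure(list(
    patients = patients,
    diagnoses = diagnoses,
    labs = labs %||% empty_labs,
    drugs = drugs %||% data.frame(rx_id = character(0),
                                  patient_id = character(0),
                                  visit_id = character(0),
                                  drug_code = character(0),
                                  drug_name = character(0),
                                  rx_date = character(0),
                                  stringsAsFactors = FALSE),
    procedures = data.frame(proc_id = character(0), patient_id = character(0),
                            proc_name = character(0), proc_date = character(0),
                            stringsAsFactors = FALSE),
    hsct = data.frame(hsct_id = character(0), patient_id = character(0),
                      hsct_date = character(0), donor_type = character(0),
                      stringsAsFactors = FALSE),
    visits = visits %||% data.frame(visit_id = character(0),
                                    patient_id = character(0),
                                    visit_date = character(0),
                                    visit_type = character(0),
                                    dept_code = character(0),
                                    stringsAsFactors = FALSE),
    deaths = data.frame(patient_id = character(0), death_date = character(0),
                        stringsAsFactors = FALSE),
    provenance = list(profile = "micro", seed = 0L, n = nrow(patients),
                      decoy_ids = character(0),
                      real_ids = patients$patient_id)
  ), class = "source_extract")
}

micro_patient <- function(pid, birth, death = "")
  data.frame(patient_id = pid, birth_date = birth, sex = "F",
             death_date = death, stringsAsFactors = FALSE)

micro_dx <- function(pid, icd, date, id = paste0("D", seq_along(pid)))
  data.frame(dx_id = id, patient_id = pid, icd10 = icd, diag_date = date,
             stringsAsFactors = FALSE)

micro_blast <- function(pid, value, date, id = paste0("L", seq_along(pid)))
  data.frame(lab_id = id, patient_id = pid, visit_id = "", lab_type = "BLAST",
             lab_date = date, value_num = as.character(value), value_text = "",
             is_narrative = "0", probe_symbol = "", copy_number = "",
             lineage = "", stringsAsFactors = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
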