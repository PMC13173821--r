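test_that("cohort generation is deterministic for a fixed seed", {
  a <- generate_cohort(60, profile_narrative_heavy(), seed = 42)
  b <- generate_cohort(60, profile_narrative_heavy(), seed = 42)
  expect_identical(a, b)
  c <- generate_cohort(60, profile_narrative_heavy(), seed = 43)
  expect_false(identical(a$patients, c$patients))
})

test_that("the narrative fraction controls free-text lab storage", {
  tab <- generate_cohort(50, profile_tabular(), seed = 1)
  expect_equal(sum(tab$labs$is_narrative == "1"), 0)
  expect_true(all(tab$labs$value_text == ""))
  narr <- generate_cohort(
    50, institution_profile("all_text", 1, 2000), seed = 1)
  cyto <- narr$labs[narr$labs$lab_type %in% c("KARYOTYPE", "FISH", "FLOW"), ]
  expect_true(all(cyto$is_narrative == "1"))
  expect_true(all(nzchar(cyto$value_text)))
})

test_that("decoy share is honoured and decoys each violate one criterion", {
  ex <- generate_cohort(200, profile_narrative_heavy(), seed = 7,
                        decoy_fraction = 0.2)
  decoys <- ex$provenance$decoy_ids
  expect_length(decoys, 40)
  # independent scan: every decoy fails at least one eligibility criterion
  for (pid in decoys) {
    dx <- ex$diagnoses[ex$diagnoses$patient_id == pid, ]
    all_dx <- dx[dx$icd10 == "C91.0", ]
    ok <- nrow(all_dx) > 0
    if (ok) {
      first <- min(all_dx$diag_date)
      birth <- ex$patients$birth_date[ex$patients$patient_id == pid]
      age <- as.integer(floor(as.numeric(
        as.Date(first) - as.Date(birth)) / 365.25))
      blasts <- as.numeric(ex$labs$value_num[
        ex$labs$patient_id == pid & ex$labs$lab_type == "BLAST"])
      has_flow <- any(ex$labs$patient_id == pid & ex$labs$lab_type == "FLOW")
      ok <- age < 18 && (any(blasts >= 20) || has_flow)
    }
    expect_false(ok, info = pid)
  }
  # and the selected cohort is exactly the non-decoys
  sel <- select_patients(ex)
  expect_setequal(sel$included, ex$provenance$real_ids)
})

test_that("clean extracts carry no quality defects", {
  run <- run_pipeline(list(n = 60, profile = "narrative_heavy", seed = 5))
  expect_equal(run$dq_before$report$total_errors, 0)
  expect_equal(nrow(run$ledger), 0)
  expect_true(run$grading$pass)
})

test_that("error injection hits exactly the requested counts with a full ledger", {
  ex <- generate_cohort(150, profile_narrative_heavy(), seed = 9)
  spec <- list(completeness = 4, validity_range = 3, validity_format = 2,
               timeline = 3, business_rule = 2, uniqueness = 2,
               relationship = 3)
  inj <- inject_errors(ex, spec, seed = 10)
  expect_equal(nrow(inj$ledger), sum(unlist(spec)))
  for (nm in names(spec))
    expect_equal(sum(inj$ledger$dimension == nm), spec[[nm]], info = nm)
  # no two injections on the same cell
  cells <- paste(inj$ledger$table, inj$ledger$row_id, inj$ledger$column)
  expect_false(anyDuplicated(cells) > 0)
  # worked examples: range defects write 27/28 against the 1-26 domain,
  # timeline defects put an event after the recorded death date
  rng <- inj$ledger[inj$ledger$dimension == "validity_range", ]
  vals <- inj$extract$visits$dept_code[
    match(rng$row_id, inj$extract$visits$visit_id)]
  expect_true(all(vals %in% c("27", "28")))
  tl <- inj$ledger[inj$ledger$dimension == "timeline", ]
  for (lid in tl$row_id) {
    row <- inj$extract$labs[inj$extract$labs$lab_id == lid, ]
    dd <- inj$extract$deaths$death_date[
      inj$extract$deaths$patient_id == row$patient_id]
    expect_true(as.Date(row$lab_date) > as.Date(dd))
  }
  # business-rule defects delete the methotrexate partner of a pair
  br <- inj$ledger[inj$ledger$dimension == "business_rule", ]
  for (rid in br$row_id) {
    lv <- inj$extract$drugs[inj$extract$drugs$rx_id == rid, ]
    expect_equal(lv$drug_code, "LV")
    expect_false(any(inj$extract$drugs$patient_id == lv$patient_id &
                       inj$extract$drugs$drug_code == "MTX"))
  }
})

test_that("an all-zero error spec is the identity", {
  ex <- generate_cohort(30, profile_tabular(), seed = 3)
  inj <- inject_errors(ex, list(), seed = 4)
  expect_identical(inj$extract, ex)
  expect_equal(nrow(inj$ledger), 0)
})

test_that("infeasible injection requests fail naming the dimension", {
  ex <- generate_cohort(10, profile_tabular(), seed = 3, death_fraction = 0)
  expect_error(inject_errors(ex, list(timeline = 5), seed = 1), "timeline")
  expect_error(inject_errors(ex, list(completeness = 10000), seed = 1),
               "completeness")
  expect_error(inject_errors(ex, list(bogus = 1), seed = 1), "unknown dimension")
  expect_error(generate_cohort(0), "positive")
})

test_that("extracts survive a CSV round-trip", {
  ex <- generate_cohort(25, profile_narrative_heavy(), seed = 13)
  dir <- withr::local_tempdir()
  write_extract(ex, dir)
  back <- read_extract(dir)
  for (rel in c("patients", "diagnoses", "labs", "drugs", "visits"))
    expect_equal(back[[rel]], ex[[rel]], info = rel)
})
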