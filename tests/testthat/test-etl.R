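test_that("cohort selection enforces the age, window and evidence criteria", {
  pats <- rbind(micro_patient("P1", "2000-06-01"),   # age 17 at dx
                micro_patient("P2", "1999-05-01"),   # age 18 at dx
                micro_patient("P3", "2010-01-01"),   # blast below threshold
                micro_patient("P4", "2012-01-01"),   # dx outside window
                micro_patient("P5", "2011-01-01"))   # earlier C92.x code
  dx <- rbind(micro_dx("P1", "C91.0", "2017-08-01", "D1"),
              micro_dx("P2", "C91.0", "2017-06-01", "D2"),
              micro_dx("P3", "C91.0", "2018-01-01", "D3"),
              micro_dx("P4", "C91.0", "2024-03-01", "D4"),
              micro_dx("P5", "C92.1", "2016-01-01", "D5"),
              micro_dx("P5", "C91.0", "2017-01-01", "D6"))
  labs <- rbind(micro_blast("P1", 25, "2017-08-01", "L1"),
                micro_blast("P2", 90, "2017-06-01", "L2"),
                micro_blast("P3", 12, "2018-01-01", "L3"),
                micro_blast("P4", 80, "2024-03-01", "L4"),
                micro_blast("P5", 40, "2017-01-01", "L5"))
  sel <- select_patients(micro_extract(pats, dx, labs))
  expect_setequal(sel$included, c("P1", "P5"))
  expect_equal(sel$review_flagged, "P5")
  expect_true(any(grepl("age 18", sel$exclusions$reason)))
  expect_true(any(grepl("1990-2023", sel$exclusions$reason)))
  expect_true(any(grepl("confirmatory", sel$exclusions$reason)))
})

test_that("exact age-18 boundary is evaluated at the first C91.0 date", {
  # birthday on the diagnosis date: completed age is exactly 18 -> excluded
  pats <- rbind(micro_patient("A", "2000-03-10"),
                micro_patient("B", "2000-03-11"))
  dx <- rbind(micro_dx("A", "C91.0", "2018-03-10", "D1"),
              micro_dx("B", "C91.0", "2018-03-10", "D2"))
  labs <- rbind(micro_blast("A", 50, "2018-03-10", "L1"),
                micro_blast("B", 50, "2018-03-10", "L2"))
  sel <- select_patients(micro_extract(pats, dx, labs))
  expect_equal(sel$included, "B")
})

test_that("an immunophenotype can stand in for the blast criterion", {
  pats <- micro_patient("P9", "2012-01-01")
  dx <- micro_dx("P9", "C91.0", "2019-01-01", "D9")
  labs <- data.frame(lab_id = "L9", patient_id = "P9", visit_id = "",
                     lab_type = "FLOW", lab_date = "2019-01-01",
                     value_num = "", value_text = "Blasts CD19+, CD10+",
                     is_narrative = "1", probe_symbol = "", copy_number = "",
                     lineage = "", stringsAsFactors = FALSE)
  sel <- select_patients(micro_extract(pats, dx, labs))
  expect_equal(sel$included, "P9")
})

test_that("missing relations raise input errors", {
  ex <- micro_extract(micro_patient("P1", "2010-01-01"),
                      micro_dx("P1", "C91.0", "2015-01-01"))
  ex$diagnoses <- NULL
  expect_error(select_patients(ex), "diagnoses")
})

test_that("direct transforms recode and type-check values", {
  src <- data.frame(patient_id = c("P1", "P2", "P3"),
                    sex = c("M", "F", "M"),
                    when = c("2020-01-01", "2023-13-01", "2021-05-05"),
                    stringsAsFactors = FALSE)
  sex_el <- structure(list(element_id = "sex", data_type = "code"),
                      class = "data_element_spec")
  out <- apply_direct(list(column = "sex", transform = "sex_code"), src, sex_el)
  expect_equal(out$value, c("1", "2", "1"))
  expect_false(any(out$format_issue))

  date_el <- structure(list(element_id = "d", data_type = "date"),
                       class = "data_element_spec")
  dates <- apply_direct(list(column = "when"), src, date_el)
  # the impossible calendar date is retained but flagged, not dropped
  expect_equal(dates$value[2], "2023-13-01")
  expect_equal(dates$format_issue, c(FALSE, TRUE, FALSE))

  empty <- apply_direct(list(column = "sex"), src[0, ], sex_el)
  expect_equal(nrow(empty), 0)
  expect_error(apply_direct(list(column = "ghost"), src, sex_el),
               "unknown source column")
})

test_that("nearest-lab transform matches a brute-force scan with stated tie-breaks", {
  ex <- generate_cohort(40, profile_narrative_heavy(), seed = 21)
  sch <- load_schema(system.file("extdata", "demo", "demo_schema.yaml",
                                 package = "allregistry"))
  store <- build_registry(ex, sch,
                          system.file("extdata", "demo", "demo_mappings.yaml",
                                      package = "allregistry"))
  dxt <- store$tables$diagnosis_all
  for (i in seq_len(nrow(dxt))) {
    pid <- dxt$dx_person_id[i]
    anchor <- as.Date(dxt$diag_date[i])
    cand <- ex$labs[ex$labs$patient_id == pid & ex$labs$lab_type == "WBC", ]
    delta <- as.numeric(as.Date(cand$lab_date) - anchor)
    keep <- delta >= 0 & delta <= 7
    expected <- if (!any(keep)) "" else {
      cand <- cand[keep, ]; delta <- delta[keep]
      ord <- order(abs(delta), delta)
      cand$value_num[ord[1]]
    }
    expect_equal(dxt$wbc_at_dx[i], expected, info = pid)
  }
})

test_that("nearest-lab tie-breaks are deterministic", {
  labs <- data.frame(
    lab_id = c("L1", "L2", "L3"), patient_id = "P1", visit_id = "",
    lab_type = "WBC", lab_date = c("2020-01-05", "2020-01-03", "2020-01-03"),
    value_num = c("9", "7", "5"), value_text = "", is_narrative = "0",
    probe_symbol = "", copy_number = "", lineage = "",
    stringsAsFactors = FALSE)
  # distances 5, 3, 3: nearest wins; among equals the stable input order
  res <- nearest_lab_value(labs, "P1", "WBC", "2019-12-31", window_days = 7)
  expect_equal(res$source_row, "L2")
  # outside the closed window: nothing qualifies
  none <- nearest_lab_value(labs, "P1", "WBC", "2019-12-20", window_days = 7)
  expect_equal(none$value, "")
})

test_that("registry build is deterministic with complete provenance", {
  ex <- generate_cohort(30, profile_tabular(), seed = 31)
  sch <- load_schema(system.file("extdata", "demo", "demo_schema.yaml",
                                 package = "allregistry"))
  mp <- system.file("extdata", "demo", "demo_mappings.yaml",
                    package = "allregistry")
  s1 <- build_registry(ex, sch, mp)
  s2 <- build_registry(ex, sch, mp)
  expect_identical(s1$tables, s2$tables)
  for (nm in names(s1$tables)) {
    prov <- s1$provenance[[nm]]
    expect_equal(nrow(prov), nrow(s1$tables[[nm]]), info = nm)
    expect_true(all(nzchar(prov$source_row)), info = nm)
  }
})

test_that("removing a decoy leaves other patients' registry rows unchanged", {
  ex <- generate_cohort(30, profile_tabular(), seed = 33)
  decoy <- ex$provenance$decoy_ids[1]
  sch <- load_schema(system.file("extdata", "demo", "demo_schema.yaml",
                                 package = "allregistry"))
  mp <- system.file("extdata", "demo", "demo_mappings.yaml",
                    package = "allregistry")
  full <- build_registry(ex, sch, mp)
  pruned <- ex
  for (rel in c("patients", "diagnoses", "labs", "drugs", "procedures",
                "hsct", "visits", "deaths"))
    pruned[[rel]] <- pruned[[rel]][pruned[[rel]]$patient_id != decoy, ,
                                   drop = FALSE]
  pruned$provenance$decoy_ids <- setdiff(pruned$provenance$decoy_ids, decoy)
  rebuilt <- build_registry(pruned, sch, mp)
  for (nm in names(full$tables)) {
    a <- full$tables[[nm]]; b <- rebuilt$tables[[nm]]
    rownames(a) <- rownames(b) <- NULL
    expect_equal(a, b, info = nm)
  }
})

test_that("a missing source relation demotes its elements with a warning", {
  ex <- generate_cohort(20, profile_tabular(), seed = 35)
  ex$hsct <- NULL
  sch <- load_schema(system.file("extdata", "demo", "demo_schema.yaml",
                                 package = "allregistry"))
  mp <- system.file("extdata", "demo", "demo_mappings.yaml",
                    package = "allregistry")
  expect_warning(store <- build_registry(ex, sch, mp), "unavailable")
  expect_equal(nrow(store$tables$hsct), 0)
  expect_true("hsct_date" %in% store$unavailable_elements)
})

test_that("unmapped automatable elements abort the build", {
  ex <- generate_cohort(10, profile_tabular(), seed = 36)
  sch <- load_schema(system.file("extdata", "demo", "demo_schema.yaml",
                                 package = "allregistry"))
  cfg <- yaml::read_yaml(system.file("extdata", "demo", "demo_mappings.yaml",
                                     package = "allregistry"))
  cfg$mappings[[1]]$elements <-
    cfg$mappings[[1]]$elements[-2]  # drop the sex mapping
  expect_error(build_registry(ex, sch, cfg), "sex")
})
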