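demo_store <- function(n = 60, seed = 51, errors = list()) {
  ex <- generate_cohort(n, profile_narrative_heavy(), seed = seed)
  inj <- inject_errors(ex, errors, seed = seed + 1)
  sch <- load_schema(system.file("extdata", "demo", "demo_schema.yaml",
                                 package = "allregistry"))
  store <- build_registry(inj$extract, sch,
                          system.file("extdata", "demo", "demo_mappings.yaml",
                                      package = "allregistry"))
  list(store = store, ledger = inj$ledger, extract = inj$extract,
       rules = load_rules(system.file("extdata", "demo", "demo_rules.yaml",
                                      package = "allregistry")))
}

test_that("error-rate arithmetic reproduces the published tallies", {
  # overall rates from the published per-indicator counts
  a_before <- published_dq_counts("site_a", "before")
  expect_equal(sum(a_before$errors), 409022)
  expect_equal(sum(a_before$checked), 22013138)
  expect_equal(overall_error_rate(sum(a_before$errors),
                                  sum(a_before$checked))$display, 1.858)
  b_before <- published_dq_counts("site_b", "before")
  expect_equal(sum(b_before$errors), 73725)
  expect_equal(overall_error_rate(sum(b_before$errors),
                                  sum(b_before$checked))$display, 0.129)
  br <- b_before[b_before$subdimension == "business_rule", ]
  expect_equal(indicator_error_rate(br$errors, br$checked)$display, 2.734)
  rel <- b_before[b_before$subdimension == "relationship", ]
  expect_equal(indicator_error_rate(rel$errors, rel$checked)$display, 0.954)
  # degenerate cases
  expect_equal(overall_error_rate(0, 100)$percent, 0)
  expect_error(overall_error_rate(1, 0), "checked")
  expect_error(overall_error_rate(5, 4), "exceed")
})

test_that("a report built from published counts grades as expected", {
  a_after <- published_dq_counts("site_a", "after")
  rep <- quality_report_from_counts(a_after)
  expect_equal(rep$total_errors, 84)
  expect_lte(rep$overall_error_rate, 0.001)
  expect_equal(rep$grading$level, 5)
  expect_true(rep$grading$pass)
})

test_that("level grading uses the inclusive 85-100 band", {
  expect_true(grade(99.999)$pass)
  expect_equal(grade(85)$level, 5)
  expect_true(grade(85)$pass)
  expect_false(grade(80)$pass)
  expect_equal(grade(80)$level, 4)
  expect_equal(grade(10)$level, 1)
  # via a report: 15% overall error -> quality value 85, boundary pass
  rep <- quality_report_from_counts(data.frame(
    dimension = "completeness", subdimension = "-", checked = 100,
    errors = 15))
  expect_equal(rep$quality_value, 85)
  expect_true(rep$grading$pass)
})

test_that("each worked defect type raises a finding of its dimension", {
  d <- demo_store(n = 80, seed = 61,
                  errors = list(completeness = 2, validity_range = 2,
                                validity_format = 1, timeline = 2,
                                business_rule = 2, uniqueness = 1,
                                relationship = 2))
  ev <- evaluate_quality(d$rules, d$store)
  got <- unique(paste(ev$findings$dimension, ev$findings$subdimension))
  expect_setequal(got, c("completeness -", "validity range",
                         "validity format", "accuracy timeline",
                         "accuracy business_rule", "uniqueness -",
                         "consistency relationship"))
  ind <- ev$report$indicators
  expect_equal(ind$errors[ind$subdimension == "range"], 2)
  expect_equal(ind$errors[ind$subdimension == "business_rule"], 2)
  expect_equal(ev$report$total_errors, sum(ind$errors))
})

test_that("the ledger oracle holds: findings and injections are a bijection", {
  for (seed in c(71, 72)) {
    d <- demo_store(n = 100, seed = seed,
                    errors = list(completeness = 3, validity_range = 3,
                                  validity_format = 2, timeline = 2,
                                  business_rule = 3, uniqueness = 2,
                                  relationship = 3))
    ev <- evaluate_quality(d$rules, d$store)
    m <- match_ledger(ev$findings, d$ledger)
    expect_equal(m$recall, 1, info = seed)
    expect_equal(m$precision, 1, info = seed)
    expect_equal(nrow(ev$findings), nrow(d$ledger), info = seed)
  }
})

test_that("remediation clears everything except business-rule findings", {
  d <- demo_store(n = 80, seed = 81,
                  errors = list(completeness = 3, validity_range = 2,
                                validity_format = 2, timeline = 2,
                                business_rule = 4, uniqueness = 2,
                                relationship = 2))
  ev <- evaluate_quality(d$rules, d$store)
  rem <- remediate(d$store, ev$findings, d$rules,
                   reference = d$extract$deaths)
  ev2 <- evaluate_quality(d$rules, rem$store)
  expect_equal(ev2$report$total_errors, 4)
  expect_true(all(ev2$findings$subdimension == "business_rule"))
  # a second remediation is a no-op on the data
  rem2 <- remediate(rem$store, ev2$findings, d$rules,
                    reference = d$extract$deaths)
  expect_identical(rem2$store$tables, rem$store$tables)
  ev3 <- evaluate_quality(d$rules, rem2$store)
  expect_equal(ev3$report$total_errors, 4)
})

test_that("remediating a clean registry is the identity", {
  d <- demo_store(n = 40, seed = 91)
  ev <- evaluate_quality(d$rules, d$store)
  expect_equal(ev$report$total_errors, 0)
  rem <- remediate(d$store, ev$findings, d$rules)
  expect_identical(rem$store$tables, d$store$tables)
})

test_that("adding defects never decreases indicator error counts", {
  base_spec <- list(completeness = 2, validity_range = 1, timeline = 1)
  more_spec <- list(completeness = 4, validity_range = 2, timeline = 1,
                    uniqueness = 1)
  d1 <- demo_store(n = 80, seed = 95, errors = base_spec)
  d2 <- demo_store(n = 80, seed = 95, errors = more_spec)
  e1 <- evaluate_quality(d1$rules, d1$store)$report$indicators
  e2 <- evaluate_quality(d2$rules, d2$store)$report$indicators
  expect_true(all(e2$errors >= e1$errors))
})

test_that("rule validation rejects illegal configurations", {
  ok <- list(rules = list(list(id = "r1", dimension = "validity",
                               subdimension = "range", table = "visit",
                               element = "dept_code", check = "range",
                               min = 1, max = 26,
                               remediation = "exclude_invalid")))
  expect_length(load_rules(ok), 1)
  bad_sub <- ok
  bad_sub$rules[[1]]$subdimension <- "timeline"
  expect_error(load_rules(bad_sub), "not legal")
  br <- list(rules = list(list(id = "b", dimension = "accuracy",
                               subdimension = "business_rule", table = "drug",
                               check = "drug_pair_within",
                               remediation = "drop_record")))
  expect_error(load_rules(br), "flag_only")
  dup <- ok
  dup$rules <- c(dup$rules, dup$rules)
  expect_error(load_rules(dup), "duplicate rule")
  # unknown scope fails before evaluation
  d <- demo_store(n = 10, seed = 96)
  ghost <- ok
  ghost$rules[[1]]$table <- "ghost"
  expect_error(evaluate_quality(load_rules(ghost), d$store), "unknown table")
  ghost_el <- ok
  ghost_el$rules[[1]]$element <- "nope"
  expect_error(evaluate_quality(load_rules(ghost_el), d$store),
               "unknown element")
})

test_that("checked-unit denominators follow the declared unit semantics", {
  d <- demo_store(n = 50, seed = 97)
  ev <- evaluate_quality(d$rules, d$store)
  ind <- ev$report$indicators
  st <- d$store$tables
  # business-rule unit: leucovorin trigger rows
  expect_equal(ind$checked[ind$subdimension == "business_rule"],
               sum(st$drug$drug_code == "LV"))
  # uniqueness unit: keys of the three covered tables
  expect_equal(ind$checked[ind$dimension == "uniqueness"],
               nrow(st$person) + nrow(st$visit) + nrow(st$drug))
  # timeline unit: event rows of deceased patients only
  dead <- st$person$person_id[nzchar(st$person$death_date)]
  n_pairs <- sum(st$visit$visit_person_id %in% dead) +
    sum(st$lab_peripheral_blood$pb_person_id %in% dead) +
    sum(st$lab_bone_marrow$bm_person_id %in% dead)
  expect_equal(ind$checked[ind$subdimension == "timeline"], n_pairs)
})
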