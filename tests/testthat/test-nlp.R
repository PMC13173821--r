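test_that("nuc ish parsing extracts probe copy numbers and calls", {
  f <- parse_fish("nuc ish(CDKN2Ax0,D9Z5 × 2)(170/300)")
  expect_equal(nrow(f), 2)
  expect_equal(f$probe, c("CDKN2A", "D9Z5"))
  expect_equal(f$copy_number, c(0L, 2L))
  expect_equal(f$call, c("deletion", "normal"))
  expect_equal(f$cells_abnormal, c(170L, 170L))
  expect_equal(f$cells_scored, c(300L, 300L))

  g <- parse_fish("nuc ish(ABL1x2,BCRx2)")
  expect_true(all(g$call == "normal"))
  expect_true(all(is.na(g$cells_abnormal)))

  gain <- parse_fish("nuc ish(KMT2Ax3)")
  expect_equal(gain$call, "gain")
})

test_that("fish parser is total: unparseable content yields indeterminate", {
  for (txt in c("no metaphases obtained", "", "nuc ish()", "46,XX",
                "nuc ish(?, ??)")) {
    f <- parse_fish(txt)
    expect_equal(f$call, "indeterminate", info = txt)
    expect_equal(f$raw, txt)
  }
  expect_error(parse_fish(NULL), "NULL")
  expect_equal(parse_fish(NA_character_)$call, "indeterminate")
})

test_that("glyph and whitespace variants parse identically", {
  base <- parse_fish("nuc ish(CDKN2Ax0,D9Z5x2)(170/300)")
  variants <- c("nuc ish(CDKN2A×0,D9Z5 × 2)(170/300)",
                "nuc  ish ( CDKN2A x 0 , D9Z5  x  2 ) (170/300)",
                "nuc ish(CDKN2Ax0,D9Z5x2)(170/300) ...")
  for (v in variants) {
    f <- parse_fish(v)
    expect_equal(f[, c("probe", "copy_number", "call", "cells_abnormal")],
                 base[, c("probe", "copy_number", "call", "cells_abnormal")],
                 info = v)
  }
})

test_that("karyotype counts and ploidy classes follow the thresholds", {
  k <- parse_karyotype("43(X, Y) ...")
  expect_equal(k$chromosome_count, 43L)
  expect_equal(k$ploidy_class, "hypodiploid")

  expect_equal(parse_karyotype("46,XX")$ploidy_class, "normal_range")
  expect_equal(parse_karyotype("55,XY,+4,+6,+10")$chromosome_count, 55L)
  expect_equal(parse_karyotype("55,XY,+4,+6,+10")$ploidy_class, "hyperdiploid")
  # boundary counts under the defaults: 44 and 50 are normal range
  expect_equal(parse_karyotype("44,XX")$ploidy_class, "normal_range")
  expect_equal(parse_karyotype("50,XY")$ploidy_class, "normal_range")
  expect_equal(parse_karyotype("51,XY")$ploidy_class, "hyperdiploid")
  # integer range takes the first bound
  expect_equal(parse_karyotype("44-46,XY")$chromosome_count, 44L)
  # no parsable count
  expect_equal(parse_karyotype("poor quality, no metaphases")$ploidy_class,
               "indeterminate")
  expect_error(parse_karyotype(NA_character_), "non-NA")
  # configurable thresholds
  k2 <- parse_karyotype("47,XX", thresholds = list(hypodiploid_below = 48,
                                                   hyperdiploid_above = 60))
  expect_equal(k2$ploidy_class, "hypodiploid")
})

test_that("immunophenotype lineage follows the marker lexicon", {
  expect_equal(parse_immunophenotype("CD19+, CD10+")$lineage, "B cell")
  expect_equal(parse_immunophenotype("cytoplasmic CD3+, CD7+")$lineage,
               "T cell")
  mixed <- parse_immunophenotype("CD19+ with aberrant CD7+")
  expect_equal(mixed$lineage, "Mixed")
  expect_true(all(c("CD19", "CD7") %in% mixed$evidence))
  expect_equal(parse_immunophenotype("specimen inadequate")$lineage,
               "unavailable")
  # negative markers and longer tokens are not evidence
  expect_equal(parse_immunophenotype("CD19-, CD30+")$lineage, "unavailable")
  expect_error(parse_immunophenotype("CD19+", lexicon = character(0)),
               "empty lexicon")
})

test_that("generator grammar round-trips through the parsers", {
  set.seed(401)
  probes <- c("CDKN2A", "ETV6", "RUNX1", "BCR", "ABL1", "KMT2A", "D9Z5")
  for (i in 1:200) {
    k <- sample(1:3, 1)
    ps <- sample(probes, k)
    cp <- sample(0:4, k, replace = TRUE)
    ca <- sample(10:290, 1)
    s <- render_fish_report(ps, cp, ca, 300,
                            glyph = sample(c("x", "×"), 1),
                            pad = sample(0:2, 1),
                            ellipsis = runif(1) < 0.5)
    f <- parse_fish(s)
    expect_equal(f$probe, ps, info = s)
    expect_equal(f$copy_number, cp, info = s)
    expect_equal(unique(f$cells_abnormal), ca, info = s)

    cnt <- sample(30:70, 1)
    ks <- render_karyotype_report(cnt, sample(c("XX", "XY"), 1),
                                  style = sample(c("iscn", "prose"), 1))
    expect_equal(parse_karyotype(ks)$chromosome_count, cnt, info = ks)

    lin <- sample(c("B cell", "T cell", "Mixed", "unavailable"), 1)
    fs <- render_flow_report(lin)
    expect_equal(parse_immunophenotype(fs)$lineage, lin, info = fs)
  }
})

test_that("parsers never raise on arbitrary strings", {
  set.seed(77)
  alphabet <- c(letters, LETTERS, 0:9, "(", ")", ",", "/", "x", "×",
                "+", "-", " ", ".", ";")
  for (i in 1:300) {
    s <- paste(sample(alphabet, sample(0:40, 1), replace = TRUE),
               collapse = "")
    expect_no_error(parse_fish(s))
    if (!is.na(s) && length(s) == 1) expect_no_error(parse_karyotype(s))
    expect_no_error(parse_immunophenotype(s))
  }
})
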