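# Deterministic synthetic CDW extracts in two institutional dialects, plus
# ground-truth error injection. The generator emulates the structural and
# statistical features the pipeline consumes (coded diagnoses, narrative vs
# tabular laboratory results, drug pairs, HSCT events, death dates, decoy
# patients) — not clinical realism beyond that.

#' Institutional CDW profile
#'
#' Describes how a source institution stores its data: the fraction of
#' cytogenetic/immunophenotype laboratory results held as narrative text
#' rather than discrete columns, and the first year covered by the CDW.
#'
#' @param name profile label.
#' @param narrative_lab_fraction proportion in `[0, 1]` of cytogenetic and
#'   flow-cytometry results stored as free text.
#' @param coverage_start_year first calendar year present in the CDW.
#' @param available_elements optional character vector restricting which
#'   registry elements this CDW can supply (`NULL` = unrestricted).
#' @return an `institution_profile` object.
#' @export
institution_profile <- function(name, narrative_lab_fraction,
                                coverage_start_year,
                                available_elements = NULL) {
  frac <- as.numeric(narrative_lab_fraction)
  if (is.na(frac) || frac < 0 || frac > 1)
    stop_input("narrative_lab_fraction must be in [0, 1]")
  structure(list(name = as.character(name),
                 narrative_lab_fraction = frac,
                 coverage_start_year = as.integer(coverage_start_year),
                 available_elements = available_elements),
            class = "institution_profile")
}

#' @describeIn institution_profile Narrative-heavy dialect: broad coverage
#'   from 2000 onward but cytogenetics and flow results mostly free text.
#' @export
profile_narrative_heavy <- function() {
  institution_profile("narrative_heavy", narrative_lab_fraction = 0.8,
                      coverage_start_year = 2000L)
}

#' @describeIn institution_profile Tabular dialect: narrower coverage from
#'   2009 onward, results fully discrete.
#' @export
profile_tabular <- function() {
  institution_profile("tabular", narrative_lab_fraction = 0,
                      coverage_start_year = 2009L)
}

# ---------------------------------------------------------------------------
# Narrative report template grammars. These mirror the parsers' grammars and
# add controlled noise (glyph choice, spacing, trailing ellipses) so parser
# robustness is testable; rendering is deterministic given its arguments.

#' Render a 'nuc ish' FISH report string
#'
#' @param probes character vector of probe symbols.
#' @param copies integer vector of copy numbers (same length).
#' @param cells_abnormal,cells_scored optional scored-cell fraction.
#' @param glyph multiplication glyph, `"x"` or `"×"`.
#' @param pad extra internal spaces (0–2).
#' @param ellipsis append a trailing " ..." fragment.
#' @return a single report string that [parse_fish()] maps back to exactly
#'   these parameters.
#' @export
render_fish_report <- function(probes, copies, cells_abnormal = NA,
                               cells_scored = NA, glyph = "x", pad = 0,
                               ellipsis = FALSE) {
  stopifnot(length(probes) == length(copies))
  sp <- strrep(" ", pad)
  toks <- paste0(probes, sp, glyph, sp, copies)
  s <- paste0("nuc ish", sp, "(", paste(toks, collapse = ","), ")")
  if (!is.na(cells_abnormal) && !is.na(cells_scored))
    s <- paste0(s, "(", cells_abnormal, "/", cells_scored, ")")
  if (ellipsis) s <- paste0(s, " ...")
  s
}

#' Render a narrative karyotype report string
#'
#' @param count modal chromosome count.
#' @param sex_chromosomes e.g. `"XX"` or `"XY"`.
#' @param style `"iscn"` (`"46,XX"`) or `"prose"` (`"43(X, Y) ..."`).
#' @param extra optional abnormality suffix such as `"+4,+6"`.
#' @return a report string that [parse_karyotype()] maps back to `count`.
#' @export
render_karyotype_report <- function(count, sex_chromosomes = "XX",
                                    style = "iscn", extra = "") {
  if (style == "prose") {
    chars <- strsplit(sex_chromosomes, "")[[1]]
    return(paste0(count, "(", paste(chars, collapse = ", "), ") ..."))
  }
  s <- paste0(count, ",", sex_chromosomes)
  if (nzchar(extra)) s <- paste0(s, ",", extra)
  s
}

#' Render a flow-cytometry immunophenotype report string
#'
#' @param lineage `"B cell"`, `"T cell"`, `"Mixed"` or `"unavailable"`.
#' @param lexicon marker lexicon used to pick positive markers.
#' @param n_markers number of positive markers per represented lineage.
#' @return a report string whose [parse_immunophenotype()] lineage is
#'   `lineage`.
#' @export
render_flow_report <- function(lineage, lexicon = default_marker_lexicon(),
                               n_markers = 2) {
  b <- names(lexicon)[lexicon == "B"]
  t <- names(lexicon)[lexicon == "T"]
  pos <- switch(lineage,
    "B cell" = b[seq_len(min(n_markers, length(b)))],
    "T cell" = t[seq_len(min(n_markers, length(t)))],
    "Mixed" = c(b[1], t[1]),
    "unavailable" = character(0))
  if (length(pos) == 0) return("Specimen inadequate; no informative markers.")
  paste0("Blasts positive for ", paste0(pos, "+", collapse = ", "), ".")
}

# ---------------------------------------------------------------------------

days_add <- function(date, days) format(parse_iso_date(date) + days, "%Y-%m-%d")

rand_date_in_year <- function(year) {
  start <- as.Date(sprintf("%04d-01-01", year))
  format(start + sample.int(365L, 1L) - 1L, "%Y-%m-%d")
}

FISH_SCENARIOS <- list(
  list(probes = c("CDKN2A", "D9Z5"), copies = c(0L, 2L)),
  list(probes = c("ETV6", "RUNX1"), copies = c(1L, 3L)),
  list(probes = c("BCR", "ABL1"), copies = c(2L, 2L)),
  list(probes = c("KMT2A", "D11Z1"), copies = c(3L, 2L))
)

#' Generate a synthetic CDW extract
#'
#' Produces one multi-relation CDW snapshot (patients, diagnoses, labs,
#' drugs, procedures, HSCT, visits, and a trusted death-certificate
#' reference relation) for `n` patients under an institutional profile.
#' Output is deterministic for fixed `(n, profile, seed)`. A configurable
#' share of patients are decoys violating exactly one eligibility criterion
#' (age at first C91.0 diagnosis >= 18, a non-C91.0 leukemia code, or marrow
#' blasts < 20% without immunophenotype evidence) so cohort selection is
#' exercised; the remaining patients carry a C91.0 diagnosis inside the
#' 1990–2023 study window, a blast percentage >= 20, narrative or tabular
#' cytogenetic/FISH/flow results at the profile's narrative fraction, WBC
#' measurements around diagnosis, and methotrexate–leucovorin prescription
#' pairs. Dates are ISO-8601 and all relation cells are character columns.
#'
#' @param n total number of patients (>= 1), decoys included.
#' @param profile an [institution_profile()].
#' @param seed integer seed; the single pseudo-random stream for this call.
#' @param decoy_fraction share of `n` generated as decoys.
#' @param hsct_fraction share of eligible patients with an HSCT event.
#' @param death_fraction share of eligible patients with a death date.
#' @param prior_malignancy_fraction share of eligible patients given an
#'   additional earlier non-ALL malignancy code (review-flag cases).
#' @return a `source_extract`: list of data.frames `patients`, `diagnoses`,
#'   `labs`, `drugs`, `procedures`, `hsct`, `visits`, `deaths`, plus a
#'   `provenance` list recording the profile, seed, sizes and decoy ids.
#' @export
generate_cohort <- function(n, profile = profile_narrative_heavy(), seed = 1L,
                            decoy_fraction = 0.2, hsct_fraction = 0.22,
                            death_fraction = 0.15,
                            prior_malignancy_fraction = 0.05) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1)
    stop_input("generate_cohort: n must be a positive integer")
  n <- as.integer(n)
  stopifnot(inherits(profile, "institution_profile"))
  with_seed(seed, {
    n_decoy <- floor(n * decoy_fraction)
    roles <- c(rep("real", n - n_decoy),
               rep(c("adult", "other_dx", "low_blast"),
                   length.out = n_decoy))
    acc <- list(patients = list(), diagnoses = list(), labs = list(),
                drugs = list(), procedures = list(), hsct = list(),
                visits = list(), deaths = list())
    ids <- new.env()
    ids$dx <- 0L; ids$lab <- 0L; ids$rx <- 0L; ids$proc <- 0L
    ids$hsct <- 0L; ids$visit <- 0L
    next_id <- function(kind, prefix) {
      ids[[kind]] <- ids[[kind]] + 1L
      sprintf("%s%06d", prefix, ids[[kind]])
    }
    year_lo <- max(1991L, profile$coverage_start_year)
    for (i in seq_len(n)) {
      role <- roles[i]
      pid <- sprintf("P%05d", i)
      diag_year <- sample(seq(year_lo, 2022L), 1L)
      diag_date <- rand_date_in_year(diag_year)
      age <- if (role == "adult") sample(18:25, 1L) else sample(1:17, 1L)
      birth_date <- days_add(diag_date, -(age * 365L + sample(0:299, 1L)))
      sex <- sample(c("M", "F"), 1L)
      icd <- if (role == "other_dx") "C92.0" else "C91.0"

      # visits: first at diagnosis, then follow-ups
      n_visit <- sample(3:6, 1L)
      offsets <- c(0L, sort(sample(1:700, n_visit - 1L)))
      vids <- character(n_visit)
      for (v in seq_len(n_visit)) {
        vids[v] <- next_id("visit", "V")
        acc$visits[[length(acc$visits) + 1L]] <- data.frame(
          visit_id = vids[v], patient_id = pid,
          visit_date = days_add(diag_date, offsets[v]),
          visit_type = sample(c("IN", "OUT"), 1L),
          dept_code = as.character(sample(1:26, 1L)),
          stringsAsFactors = FALSE)
      }

      acc$diagnoses[[length(acc$diagnoses) + 1L]] <- data.frame(
        dx_id = next_id("dx", "D"), patient_id = pid, icd10 = icd,
        diag_date = diag_date, stringsAsFactors = FALSE)
      if (role == "real" && stats::runif(1) < prior_malignancy_fraction)
        acc$diagnoses[[length(acc$diagnoses) + 1L]] <- data.frame(
          dx_id = next_id("dx", "D"), patient_id = pid, icd10 = "C92.1",
          diag_date = days_add(diag_date, -sample(30:400, 1L)),
          stringsAsFactors = FALSE)

      lab_row <- function(type, date, value_num = "", value_text = "",
                          narrative = FALSE, probe = "", copies = "",
                          lineage = "") {
        data.frame(lab_id = next_id("lab", "L"), patient_id = pid,
                   visit_id = vids[1], lab_type = type, lab_date = date,
                   value_num = as.character(value_num),
                   value_text = value_text,
                   is_narrative = as.character(as.integer(narrative)),
                   probe_symbol = probe, copy_number = as.character(copies),
                   lineage = lineage, stringsAsFactors = FALSE)
      }
      # bone-marrow blasts at diagnosis
      blast <- if (role == "low_blast") sample(3:15, 1L) else sample(20:98, 1L)
      acc$labs[[length(acc$labs) + 1L]] <- lab_row("BLAST", diag_date, blast)
      # WBC: one near diagnosis plus follow-ups
      wbc_dates <- c(days_add(diag_date, sample(0:5, 1L)),
                     days_add(diag_date, sort(sample(30:600, sample(1:3, 1L)))))
      for (wd in wbc_dates)
        acc$labs[[length(acc$labs) + 1L]] <- lab_row(
          "WBC", wd, min(round(stats::rlnorm(1, log(6), 0.9), 2), 900))
      # cytogenetics / FISH / flow, narrative at the profile's fraction
      narrative <- stats::runif(3) < profile$narrative_lab_fraction
      count <- sample(c(rep(46L, 6), 43:45, 51:58), 1L)
      if (narrative[1]) {
        style <- sample(c("iscn", "prose"), 1L)
        sx <- if (sex == "F") "XX" else "XY"
        acc$labs[[length(acc$labs) + 1L]] <- lab_row(
          "KARYOTYPE", diag_date,
          value_text = render_karyotype_report(count, sx, style = style),
          narrative = TRUE)
      } else {
        acc$labs[[length(acc$labs) + 1L]] <- lab_row(
          "KARYOTYPE", diag_date, value_num = count)
      }
      sc <- FISH_SCENARIOS[[sample(length(FISH_SCENARIOS), 1L)]]
      ca <- sample(50:250, 1L); cs <- 300L
      if (narrative[2]) {
        acc$labs[[length(acc$labs) + 1L]] <- lab_row(
          "FISH", diag_date,
          value_text = render_fish_report(
            sc$probes, sc$copies, ca, cs,
            glyph = sample(c("x", "×"), 1L), pad = sample(0:2, 1L),
            ellipsis = stats::runif(1) < 0.3),
          narrative = TRUE)
      } else {
        abn <- which(sc$copies != 2L)
        k <- if (length(abn) > 0) abn[1] else 1L
        acc$labs[[length(acc$labs) + 1L]] <- lab_row(
          "FISH", diag_date, probe = sc$probes[k], copies = sc$copies[k])
      }
      if (role != "low_blast") {
        lin <- sample(c("B cell", "T cell", "Mixed"), 1L,
                      prob = c(0.78, 0.17, 0.05))
        if (narrative[3]) {
          acc$labs[[length(acc$labs) + 1L]] <- lab_row(
            "FLOW", diag_date,
            value_text = render_flow_report(lin), narrative = TRUE)
        } else {
          acc$labs[[length(acc$labs) + 1L]] <- lab_row(
            "FLOW", diag_date, lineage = lin)
        }
      }

      # one methotrexate–leucovorin pair, plus unrelated chemotherapy
      mtx_date <- days_add(diag_date, 14L + sample(0:10, 1L))
      lv_date <- days_add(mtx_date, sample(1:3, 1L))
      rx <- function(code, name, date) data.frame(
        rx_id = next_id("rx", "R"), patient_id = pid, visit_id = vids[1],
        drug_code = code, drug_name = name, rx_date = date,
        stringsAsFactors = FALSE)
      acc$drugs[[length(acc$drugs) + 1L]] <- rx("MTX", "methotrexate", mtx_date)
      acc$drugs[[length(acc$drugs) + 1L]] <- rx("LV", "leucovorin", lv_date)
      acc$drugs[[length(acc$drugs) + 1L]] <- rx("VCR", "vincristine",
                                                days_add(diag_date, 7L))

      acc$procedures[[length(acc$procedures) + 1L]] <- data.frame(
        proc_id = next_id("proc", "S"), patient_id = pid,
        proc_name = "BM aspiration", proc_date = diag_date,
        stringsAsFactors = FALSE)

      # death (when assigned) must postdate every generated event
      last_event <- max(parse_iso_date(c(
        days_add(diag_date, max(offsets)), wbc_dates, lv_date)))
      last_event <- format(last_event, "%Y-%m-%d")
      if (role == "real" && stats::runif(1) < hsct_fraction) {
        hd <- days_add(diag_date, sample(200:600, 1L))
        acc$hsct[[length(acc$hsct) + 1L]] <- data.frame(
          hsct_id = next_id("hsct", "H"), patient_id = pid, hsct_date = hd,
          donor_type = sample(c("MSD", "MUD", "HAPLO"), 1L),
          stringsAsFactors = FALSE)
        if (parse_iso_date(hd) > parse_iso_date(last_event)) last_event <- hd
      }
      death_date <- ""
      if (role == "real" && stats::runif(1) < death_fraction) {
        death_date <- days_add(last_event, sample(30:400, 1L))
        acc$deaths[[length(acc$deaths) + 1L]] <- data.frame(
          patient_id = pid, death_date = death_date, stringsAsFactors = FALSE)
      }
      acc$patients[[length(acc$patients) + 1L]] <- data.frame(
        patient_id = pid, birth_date = birth_date, sex = sex,
        death_date = death_date, stringsAsFactors = FALSE)
    }
    bind <- function(rows, empty) {
      if (length(rows) == 0) return(empty)
      out <- do.call(rbind, rows); rownames(out) <- NULL; out
    }
    extract <- structure(list(
      patients = bind(acc$patients, data.frame()),
      diagnoses = bind(acc$diagnoses, data.frame()),
      labs = bind(acc$labs, data.frame()),
      drugs = bind(acc$drugs, data.frame()),
      procedures = bind(acc$procedures, data.frame()),
      hsct = bind(acc$hsct, data.frame(
        hsct_id = character(0), patient_id = character(0),
        hsct_date = character(0), donor_type = character(0))),
      visits = bind(acc$visits, data.frame()),
      deaths = bind(acc$deaths, data.frame(
        patient_id = character(0), death_date = character(0))),
      provenance = list(
        profile = profile$name, seed = as.integer(seed), n = n,
        narrative_lab_fraction = profile$narrative_lab_fraction,
        decoy_fraction = decoy_fraction,
        decoy_ids = sprintf("P%05d", which(roles != "real")),
        decoy_roles = roles,
        real_ids = sprintf("P%05d", which(roles == "real")))
    ), class = "source_extract")
    extract
  })
}

#' @export
print.source_extract <- function(x, ...) {
  cat(sprintf("Synthetic CDW extract: profile '%s', seed %d, %d patients (%d decoys)\n",
              x$provenance$profile, x$provenance$seed, x$provenance$n,
              length(x$provenance$decoy_ids)))
  for (rel in c("patients", "diagnoses", "labs", "drugs", "procedures",
                "hsct", "visits", "deaths"))
    cat(sprintf("  %-10s %5d rows\n", rel, nrow(x[[rel]])))
  invisible(x)
}

ERROR_DIMENSIONS <- c("completeness", "validity_range", "validity_format",
                      "timeline", "business_rule", "uniqueness",
                      "relationship")

# Map a source lab_type to the registry table it populates under the demo
# mapping configuration, and the element-id prefix used there (the injection
# ledger records expected registry locations for the downstream oracle;
# element ids are table-prefixed because they are unique across the schema).
lab_registry_map <- function(lab_type) {
  switch(lab_type,
    WBC = list(table = "lab_peripheral_blood", prefix = "pb"),
    BLAST = list(table = "lab_bone_marrow", prefix = "bm"),
    KARYOTYPE = list(table = "lab_chromosome", prefix = "chr"),
    FISH = list(table = "lab_fish", prefix = "fish"),
    FLOW = list(table = "lab_flow", prefix = "flow"))
}

#' Inject known defects into a synthetic extract
#'
#' Corrupts exactly the requested number of cells/rows per quality dimension
#' and returns the corrupted extract together with a ledger enumerating every
#' injection (source location, dimension, and the registry location where the
#' quality engine is expected to flag it). No two injections target the same
#' cell. Injections are placed only on rows of eligible (non-decoy) patients
#' and never on cells that determine cohort eligibility, so that every
#' injected defect reaches the built registry and the ledger is a complete
#' ground truth for the rule engine.
#'
#' Defect construction per dimension: `completeness` blanks a required visit
#' type; `validity_range` writes an out-of-domain department code (27/28
#' where 1–26 is valid); `validity_format` writes an impossible calendar
#' date; `timeline` moves a laboratory test date after the patient's death
#' date; `business_rule` deletes the methotrexate row of a
#' methotrexate–leucovorin pair; `uniqueness` duplicates a visit row
#' (duplicate primary key); `relationship` points a laboratory row's visit
#' foreign key at a nonexistent visit.
#'
#' @param extract a `source_extract`.
#' @param error_spec named list/vector of non-negative counts over
#'   `completeness`, `validity_range`, `validity_format`, `timeline`,
#'   `business_rule`, `uniqueness`, `relationship` (missing names = 0).
#' @param seed integer seed for target selection.
#' @return list with `extract` (corrupted copy) and `ledger` (data.frame:
#'   `table`, `row_id`, `column`, `dimension`, `description`,
#'   `registry_table`, `registry_key`, `registry_element`).
#' @export
inject_errors <- function(extract, error_spec, seed = 1L) {
  stopifnot(inherits(extract, "source_extract"))
  spec <- as.list(error_spec)
  unknown <- setdiff(names(spec), ERROR_DIMENSIONS)
  if (length(unknown) > 0)
    stop_input("inject_errors: unknown dimension(s): %s",
               paste(unknown, collapse = ", "))
  counts <- stats::setNames(integer(length(ERROR_DIMENSIONS)), ERROR_DIMENSIONS)
  for (nm in names(spec)) counts[nm] <- as.integer(spec[[nm]])
  if (any(counts < 0)) stop_input("inject_errors: counts must be >= 0")
  ledger_cols <- c("table", "row_id", "column", "dimension", "description",
                   "registry_table", "registry_key", "registry_element")
  empty_ledger <- as.data.frame(
    stats::setNames(rep(list(character(0)), length(ledger_cols)), ledger_cols),
    stringsAsFactors = FALSE)
  if (sum(counts) == 0) return(list(extract = extract, ledger = empty_ledger))

  with_seed(seed, {
    ex <- extract
    real <- ex$provenance$real_ids
    ledger <- list()
    used_visit_rows <- integer(0)   # visit rows already targeted
    used_lab_rows <- integer(0)

    add <- function(table, row_id, column, dimension, description,
                    registry_table, registry_key, registry_element) {
      ledger[[length(ledger) + 1L]] <<- data.frame(
        table = table, row_id = row_id, column = column,
        dimension = dimension, description = description,
        registry_table = registry_table, registry_key = registry_key,
        registry_element = registry_element, stringsAsFactors = FALSE)
    }
    pick_visits <- function(k, dim) {
      pool <- setdiff(which(ex$visits$patient_id %in% real), used_visit_rows)
      if (length(pool) < k)
        stop_input("inject_errors: cannot satisfy dimension '%s' (%d targets, %d available)",
                   dim, k, length(pool))
      sel <- sort(sample(pool, k))
      used_visit_rows <<- c(used_visit_rows, sel)
      sel
    }

    if (counts[["completeness"]] > 0) {
      for (r in pick_visits(counts[["completeness"]], "completeness")) {
        vid <- ex$visits$visit_id[r]
        ex$visits$visit_type[r] <- ""
        add("visits", vid, "visit_type", "completeness",
            "required visit type blanked", "visit", vid, "visit_type")
      }
    }
    if (counts[["validity_range"]] > 0) {
      for (r in pick_visits(counts[["validity_range"]], "validity_range")) {
        vid <- ex$visits$visit_id[r]
        bad <- as.character(sample(27:28, 1L))
        ex$visits$dept_code[r] <- bad
        add("visits", vid, "dept_code", "validity_range",
            sprintf("department code %s outside valid range 1-26", bad),
            "visit", vid, "dept_code")
      }
    }
    if (counts[["validity_format"]] > 0) {
      for (r in pick_visits(counts[["validity_format"]], "validity_format")) {
        vid <- ex$visits$visit_id[r]
        yr <- substr(ex$visits$visit_date[r], 1, 4)
        ex$visits$visit_date[r] <- paste0(yr, "-13-01")
        add("visits", vid, "visit_date", "validity_format",
            "visit date set to impossible calendar date", "visit", vid,
            "visit_date")
      }
    }
    if (counts[["timeline"]] > 0) {
      dead <- ex$deaths$patient_id[ex$deaths$patient_id %in% real]
      pool <- setdiff(
        which(ex$labs$lab_type == "WBC" & ex$labs$patient_id %in% dead),
        used_lab_rows)
      k <- counts[["timeline"]]
      if (length(pool) < k)
        stop_input("inject_errors: cannot satisfy dimension 'timeline' (%d targets, %d eligible lab rows of deceased patients)",
                   k, length(pool))
      sel <- sort(sample(pool, k))
      used_lab_rows <- c(used_lab_rows, sel)
      for (r in sel) {
        lid <- ex$labs$lab_id[r]
        dd <- ex$deaths$death_date[match(ex$labs$patient_id[r],
                                         ex$deaths$patient_id)]
        ex$labs$lab_date[r] <- days_add(dd, sample(10:100, 1L))
        add("labs", lid, "lab_date", "timeline",
            sprintf("test date moved after death date %s", dd),
            "lab_peripheral_blood", lid, "pb_test_date")
      }
    }
    if (counts[["business_rule"]] > 0) {
      mtx <- ex$drugs[ex$drugs$drug_code == "MTX" &
                        ex$drugs$patient_id %in% real, , drop = FALSE]
      pats <- unique(mtx$patient_id)
      k <- counts[["business_rule"]]
      if (length(pats) < k)
        stop_input("inject_errors: cannot satisfy dimension 'business_rule' (%d targets, %d patients with a methotrexate row)",
                   k, length(pats))
      for (p in sample(pats, k)) {
        drop_row <- which(ex$drugs$drug_code == "MTX" &
                            ex$drugs$patient_id == p)[1]
        lv <- ex$drugs$rx_id[ex$drugs$drug_code == "LV" &
                               ex$drugs$patient_id == p][1]
        ex$drugs <- ex$drugs[-drop_row, , drop = FALSE]
        add("drugs", lv, "", "business_rule",
            "methotrexate row of a leucovorin pair deleted", "drug", lv, "")
      }
      rownames(ex$drugs) <- NULL
    }
    if (counts[["uniqueness"]] > 0) {
      for (r in pick_visits(counts[["uniqueness"]], "uniqueness")) {
        vid <- ex$visits$visit_id[r]
        ex$visits <- rbind(ex$visits, ex$visits[r, , drop = FALSE])
        add("visits", vid, "", "uniqueness",
            "visit row duplicated (duplicate primary key)", "visit", vid, "")
      }
      rownames(ex$visits) <- NULL
    }
    if (counts[["relationship"]] > 0) {
      pool <- setdiff(which(ex$labs$patient_id %in% real &
                              ex$labs$lab_type %in% c("WBC", "BLAST")),
                      used_lab_rows)
      k <- counts[["relationship"]]
      if (length(pool) < k)
        stop_input("inject_errors: cannot satisfy dimension 'relationship' (%d targets, %d eligible lab rows)",
                   k, length(pool))
      sel <- sort(sample(pool, k))
      for (j in seq_along(sel)) {
        r <- sel[j]
        lid <- ex$labs$lab_id[r]
        ex$labs$visit_id[r] <- sprintf("VX%06d", j)
        lm <- lab_registry_map(ex$labs$lab_type[r])
        add("labs", lid, "visit_id", "relationship",
            "lab visit foreign key points at nonexistent visit",
            lm$table, lid, paste0(lm$prefix, "_visit_id"))
      }
    }
    ledger_df <- do.call(rbind, ledger)
    rownames(ledger_df) <- NULL
    list(extract = ex, ledger = ledger_df)
  })
}

#' Write a synthetic extract to a directory of CSV files
#'
#' One CSV per relation plus a JSON provenance block.
#'
#' @param extract a `source_extract`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_extract <- function(extract, dir) {
  stopifnot(inherits(extract, "source_extract"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rel in c("patients", "diagnoses", "labs", "drugs", "procedures",
                "hsct", "visits", "deaths"))
    utils::write.csv(extract[[rel]], file.path(dir, paste0(rel, ".csv")),
                     row.names = FALSE)
  jsonlite::write_json(extract$provenance,
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a synthetic extract back from CSV files
#'
#' @param dir directory written by [write_extract()].
#' @return a `source_extract`.
#' @export
read_extract <- function(dir) {
  rels <- c("patients", "diagnoses", "labs", "drugs", "procedures", "hsct",
            "visits", "deaths")
  out <- lapply(rels, function(rel) {
    f <- file.path(dir, paste0(rel, ".csv"))
    if (!file.exists(f)) stop_input("extract relation missing: %s", f)
    utils::read.csv(f, colClasses = "character")
  })
  names(out) <- rels
  pf <- file.path(dir, "provenance.json")
  out$provenance <- if (file.exists(pf))
    jsonlite::read_json(pf, simplifyVector = TRUE) else list()
  structure(out, class = "source_extract")
}
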