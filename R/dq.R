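# Declarative data-quality rule engine over five dimensions (completeness,
# validity, accuracy, uniqueness, consistency), with explicit checked-unit
# denominators, error-rate metrics, remediation policies and level grading.

DQ_DIMENSIONS <- list(
  completeness = "-",
  validity = c("range", "format"),
  accuracy = c("timeline", "business_rule"),
  uniqueness = "-",
  consistency = "relationship"
)

# canonical indicator order for reports
DQ_INDICATORS <- data.frame(
  dimension = c("completeness", "validity", "validity", "accuracy",
                "accuracy", "uniqueness", "consistency"),
  subdimension = c("-", "range", "format", "timeline", "business_rule",
                   "-", "relationship"),
  stringsAsFactors = FALSE)

REMEDIATION_POLICIES <- c("mark_na", "drop_record", "exclude_invalid",
                          "verify_date", "reload_dedupe", "reindex_fk",
                          "flag_only")

CHECK_KINDS <- c("not_null", "range", "format_date", "format_code",
                 "not_after_death", "drug_pair_within", "unique_key",
                 "fk_exists")

#' Load and validate a quality rule pack
#'
#' Reads a structured rule configuration (YAML/JSON, `rules` block). Each
#' rule declares its dimension and subdimension, the table/element scope, a
#' declarative check with parameters, the checked-unit semantics implied by
#' the check (cell, event pair, key, or reference), and a remediation policy.
#' Validation enforces the dimension/subdimension vocabulary
#' (validity: range/format; accuracy: timeline/business_rule; consistency:
#' relationship; others `-`) and that business-rule checks are flag-only.
#'
#' @param rules file path or parsed list.
#' @return list of validated rule objects (class `quality_rule`).
#' @export
load_rules <- function(rules) {
  cfg <- read_config(rules)
  if (is.null(cfg$rules) || length(cfg$rules) == 0)
    stop_input("rule pack error: no rules defined")
  out <- lapply(cfg$rules, function(r) {
    for (f in c("id", "dimension", "table", "check"))
      if (is.null(r[[f]]))
        stop_input("rule pack error: rule '%s' missing field '%s'",
                   r$id %||% "<unnamed>", f)
    dim <- r$dimension
    sub <- r$subdimension %||% "-"
    if (!dim %in% names(DQ_DIMENSIONS))
      stop_input("rule '%s': unknown dimension '%s'", r$id, dim)
    if (!sub %in% DQ_DIMENSIONS[[dim]])
      stop_input("rule '%s': subdimension '%s' not legal for dimension '%s'",
                 r$id, sub, dim)
    if (!r$check %in% CHECK_KINDS)
      stop_input("rule '%s': unknown check '%s'", r$id, r$check)
    pol <- r$remediation %||% "flag_only"
    if (!pol %in% REMEDIATION_POLICIES)
      stop_input("rule '%s': unknown remediation policy '%s'", r$id, pol)
    if (sub == "business_rule" && pol != "flag_only")
      stop_input("rule '%s': business-rule checks must be flag_only", r$id)
    structure(c(r, list(subdimension = sub, remediation = pol)),
              class = "quality_rule")
  })
  ids <- vapply(out, function(r) r$id, character(1))
  if (anyDuplicated(ids))
    stop_input("rule pack error: duplicate rule id(s): %s",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out
}

table_key_column <- function(store, table)
  store$schema$tables[[table]]$primary_key[1]

# Evaluate one rule; returns list(checked = <int>, findings = data.frame).
eval_rule <- function(rule, store) {
  tb <- store$tables[[rule$table]]
  if (is.null(tb))
    stop_input("rule '%s' references unknown table '%s'", rule$id, rule$table)
  key_col <- table_key_column(store, rule$table)
  keys <- if (nrow(tb) > 0) tb[[key_col]] else character(0)
  finding <- function(rows, element, message) {
    if (length(rows) == 0) return(NULL)
    data.frame(rule_id = rule$id, dimension = rule$dimension,
               subdimension = rule$subdimension, table = rule$table,
               row_key = keys[rows], element = element, message = message,
               remediated = FALSE, stringsAsFactors = FALSE)
  }
  el <- rule$element
  if (!is.null(el) && !el %in% names(tb))
    stop_input("rule '%s' references unknown element '%s.%s'",
               rule$id, rule$table, el)
  v <- if (!is.null(el)) as.character(tb[[el]]) else NULL

  switch(rule$check,
    not_null = {
      bad <- which(cell_missing(v))   # explicit "NA" marker passes
      list(checked = nrow(tb), findings = finding(bad, el, "missing required value"))
    },
    range = {
      present <- !cell_missing(v) & !cell_marked_na(v)
      num <- suppressWarnings(as.numeric(v))
      bad <- which(present & !is.na(num) &
                     (num < rule$min | num > rule$max))
      list(checked = nrow(tb),
           findings = finding(bad, el,
             sprintf("value outside valid range %s-%s", rule$min, rule$max)))
    },
    format_date = {
      present <- !cell_missing(v) & !cell_marked_na(v)
      bad <- which(present & !is_valid_iso_date(v))
      list(checked = nrow(tb),
           findings = finding(bad, el, "not a valid ISO-8601 calendar date"))
    },
    format_code = {
      present <- !cell_missing(v) & !cell_marked_na(v)
      bad <- which(present & !v %in% as.character(unlist(rule$codes)))
      list(checked = nrow(tb),
           findings = finding(bad, el, "code outside the defined value set"))
    },
    not_after_death = {
      person <- store$tables[[rule$person_table %||% "person"]]
      death <- person$death_date[match(tb[[rule$person_column %||% "person_id"]],
                                       person$person_id)]
      ev <- parse_iso_date(v)
      dd <- parse_iso_date(death)
      in_scope <- which(!is.na(ev) & !is.na(dd))
      bad <- in_scope[ev[in_scope] > dd[in_scope]]
      list(checked = length(in_scope),
           findings = finding(bad, el, "event date after recorded death date"))
    },
    drug_pair_within = {
      trig <- which(tb[[rule$code_column]] == rule$trigger_code)
      days <- as.numeric(rule$days %||% 7)
      req_rows <- tb[tb[[rule$code_column]] == rule$required_code, , drop = FALSE]
      pcol <- rule$person_column %||% "person_id"
      dcol <- rule$date_column
      bad <- integer(0)
      for (r in trig) {
        t_date <- parse_iso_date(tb[[dcol]][r])
        if (is.na(t_date)) next
        mt <- req_rows[req_rows[[pcol]] == tb[[pcol]][r], , drop = FALSE]
        md <- parse_iso_date(mt[[dcol]])
        ok <- any(!is.na(md) & md >= t_date - days & md <= t_date)
        if (!ok) bad <- c(bad, r)
      }
      list(checked = length(trig),
           findings = finding(bad, NA_character_,
             sprintf("%s without %s within %d prior days",
                     rule$trigger_code, rule$required_code, as.integer(days))))
    },
    unique_key = {
      bad <- which(duplicated(keys))
      list(checked = nrow(tb),
           findings = finding(bad, NA_character_, "duplicate primary key value"))
    },
    fk_exists = {
      ref <- store$tables[[rule$ref_table]]
      if (is.null(ref))
        stop_input("rule '%s' references unknown table '%s'", rule$id,
                   rule$ref_table)
      refv <- as.character(ref[[rule$ref_element]])
      present <- which(!cell_missing(v) & !cell_marked_na(v))
      bad <- present[!v[present] %in% refv]
      list(checked = length(present),
           findings = finding(bad, el,
             sprintf("reference to %s.%s not found", rule$ref_table,
                     rule$ref_element)))
    })
}

#' Evaluate a rule pack over a registry
#'
#' Applies every rule over its declared scope, counting checked units per
#' rule (cells for completeness/validity rules, qualifying event pairs for
#' timeline and business rules, keys for uniqueness, non-missing references
#' for consistency) and collecting findings in deterministic order. Rules
#' referencing unknown tables or elements fail before any evaluation.
#'
#' @param rules a rule pack from [load_rules()] (or a path/list accepted by
#'   it).
#' @param store a `registry_store`.
#' @return list with `findings` (data.frame: rule_id, dimension,
#'   subdimension, table, row_key, element, message, remediated) and
#'   `report` (a [quality_report]).
#' @export
evaluate_quality <- function(rules, store) {
  if (!is.list(rules) || length(rules) == 0 ||
      !inherits(rules[[1]], "quality_rule"))
    rules <- load_rules(rules)
  stopifnot(inherits(store, "registry_store"))
  # validate scopes up front: configuration errors precede any evaluation
  for (r in rules) {
    tb <- store$tables[[r$table]]
    if (is.null(tb))
      stop_input("rule '%s' references unknown table '%s'", r$id, r$table)
    if (!is.null(r$element) && !r$element %in% names(tb))
      stop_input("rule '%s' references unknown element '%s.%s'",
                 r$id, r$table, r$element)
  }
  findings <- list()
  tallies <- list()
  for (r in rules) {
    res <- eval_rule(r, store)
    if (!is.null(res$findings)) findings[[length(findings) + 1L]] <- res$findings
    tallies[[length(tallies) + 1L]] <- data.frame(
      dimension = r$dimension, subdimension = r$subdimension,
      checked = res$checked,
      errors = if (is.null(res$findings)) 0L else nrow(res$findings),
      stringsAsFactors = FALSE)
  }
  fdf <- if (length(findings)) do.call(rbind, findings) else data.frame(
    rule_id = character(0), dimension = character(0),
    subdimension = character(0), table = character(0),
    row_key = character(0), element = character(0), message = character(0),
    remediated = logical(0), stringsAsFactors = FALSE)
  rownames(fdf) <- NULL
  tal <- do.call(rbind, tallies)
  agg <- merge(DQ_INDICATORS,
               stats::aggregate(cbind(checked, errors) ~ dimension + subdimension,
                                data = tal, FUN = sum),
               by = c("dimension", "subdimension"), all.x = TRUE, sort = FALSE)
  agg$checked[is.na(agg$checked)] <- 0L
  agg$errors[is.na(agg$errors)] <- 0L
  # restore canonical order lost by merge
  agg <- agg[match(paste(DQ_INDICATORS$dimension, DQ_INDICATORS$subdimension),
                   paste(agg$dimension, agg$subdimension)), ]
  rownames(agg) <- NULL
  list(findings = fdf, report = quality_report_from_counts(agg))
}

#' Assemble a quality report from per-indicator tallies
#'
#' Builds the standard report object (indicator-specific and overall error
#' rates, quality value, level) from externally supplied checked/error
#' counts — the same constructor [evaluate_quality()] uses internally, so
#' published tally tables can be re-scored with the package's rate and
#' grading arithmetic.
#'
#' @param counts data.frame with columns `dimension`, `subdimension`,
#'   `checked`, `errors`.
#' @return a `quality_report`: per-indicator table with raw and 3-decimal
#'   display rates, totals, `overall_error_rate`, `quality_value`, `level`
#'   and `pass`.
#' @export
quality_report_from_counts <- function(counts) {
  stopifnot(all(c("dimension", "subdimension", "checked", "errors") %in%
                  names(counts)))
  if (any(counts$errors > counts$checked))
    stop_input("quality report: errors exceed checked count for an indicator")
  ind <- counts
  ind$error_rate <- ifelse(ind$checked > 0,
                           100 * ind$errors / ind$checked, 0)
  ind$error_rate_display <- round_half_up(ind$error_rate, 3)
  total_checked <- sum(ind$checked)
  total_errors <- sum(ind$errors)
  overall <- overall_error_rate(total_errors, total_checked)
  structure(list(
    indicators = ind,
    total_checked = total_checked,
    total_errors = total_errors,
    overall_error_rate = overall$percent,
    overall_error_rate_display = overall$display,
    quality_value = 100 - overall$percent,
    grading = grade_quality_value(100 - overall$percent)
  ), class = "quality_report")
}

#' Overall error rate
#'
#' `100 * errors / checked` over a whole registry or table: the proportion of
#' checked data units violating any quality rule. The raw percentage is
#' retained alongside a half-up 3-decimal display value.
#'
#' @param errors total number of error data units.
#' @param checked total number of checked data units (> 0).
#' @return list with `errors`, `checked`, `percent` (raw) and `display`.
#' @examples
#' overall_error_rate(409022, 22013138)  # 1.858 (display)
#' @export
overall_error_rate <- function(errors, checked) {
  if (length(checked) != 1 || is.na(checked) || checked <= 0)
    stop_input("error rate undefined: checked count must be > 0")
  if (errors > checked)
    stop_input("error rate undefined: errors exceed checked count")
  pct <- 100 * errors / checked
  list(errors = errors, checked = checked, percent = pct,
       display = round_half_up(pct, 3))
}

#' Indicator-specific error rate
#'
#' As [overall_error_rate()], per (dimension, subdimension) indicator.
#'
#' @inheritParams overall_error_rate
#' @return list with `errors`, `checked`, `percent`, `display`.
#' @examples
#' indicator_error_rate(453, 16567)  # 2.734 (display)
#' @export
indicator_error_rate <- function(errors, checked)
  overall_error_rate(errors, checked)

grade_quality_value <- function(quality_value, minimum_level = 5L) {
  bands <- data.frame(level = 5:1,
                      lo = c(85, 70, 55, 40, 0),
                      hi = c(100, 85, 70, 55, 40))
  lvl <- bands$level[quality_value >= bands$lo &
                       (quality_value < bands$hi |
                          (bands$level == 5 & quality_value <= 100))][1]
  list(quality_value = quality_value, level = lvl,
       pass = quality_value >= 85 & quality_value <= 100)
}

#' Grade a quality report
#'
#' The quality value is `100 - overall error rate`; Level 5 (quality value
#' 85–100, inclusive lower bound) is the minimum acceptable standard.
#'
#' @param report a `quality_report` (or a bare numeric quality value).
#' @return list with `quality_value`, `level` (1–5) and `pass`.
#' @export
grade <- function(report) {
  qv <- if (inherits(report, "quality_report")) report$quality_value
        else as.numeric(report)
  grade_quality_value(qv)
}

#' @export
print.quality_report <- function(x, ...) {
  cat("Data-quality report\n")
  ind <- x$indicators
  for (i in seq_len(nrow(ind)))
    cat(sprintf("  %-12s %-13s checked %12s  errors %8s  rate %7.3f%%\n",
                ind$dimension[i], ind$subdimension[i],
                format(ind$checked[i], big.mark = ","),
                format(ind$errors[i], big.mark = ","),
                ind$error_rate_display[i]))
  cat(sprintf("  TOTAL checked %s, errors %s, overall error rate %.3f%%\n",
              format(x$total_checked, big.mark = ","),
              format(x$total_errors, big.mark = ","),
              x$overall_error_rate_display))
  cat(sprintf("  quality value %.3f -> Level %d (%s)\n", x$quality_value,
              x$grading$level, if (x$grading$pass) "pass" else "fail"))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Remediation

#' Remediate quality findings
#'
#' Applies each rule's remediation policy to its findings: `mark_na` and
#' `exclude_invalid` replace the offending cell with the explicit `"NA"`
#' marker; `reindex_fk` blanks the dangling reference the same way;
#' `drop_record` removes the row; `reload_dedupe` removes duplicate-key rows
#' beyond the first; `verify_date` restores the person death date from the
#' trusted reference relation and drops event rows still conflicting;
#' `flag_only` (all business rules) logs and leaves the data untouched. When
#' several cell policies hit one cell the precedence is
#' `drop_record > exclude_invalid > mark_na`. Re-evaluating the remediated
#' registry yields findings only for flag-only rules, and a second
#' remediation is a no-op.
#'
#' @param store a `registry_store`.
#' @param findings findings from [evaluate_quality()] on this store.
#' @param rules the rule pack that produced the findings.
#' @param reference optional trusted death reference (data.frame
#'   `patient_id`, `death_date`) for `verify_date`.
#' @return list with `store` (remediated) and `log` (data.frame of actions).
#' @export
remediate <- function(store, findings, rules, reference = NULL) {
  stopifnot(inherits(store, "registry_store"))
  if (!is.list(rules) || !inherits(rules[[1]], "quality_rule"))
    rules <- load_rules(rules)
  rule_by_id <- stats::setNames(rules, vapply(rules, `[[`, character(1), "id"))
  log <- list()
  note <- function(policy, table, row_key, element, action)
    log[[length(log) + 1L]] <<- data.frame(
      policy = policy, table = table, row_key = row_key,
      element = ifelse(is.na(element), "", element), action = action,
      stringsAsFactors = FALSE)

  if (nrow(findings) == 0)
    return(list(store = store, log = data.frame(
      policy = character(0), table = character(0), row_key = character(0),
      element = character(0), action = character(0))))

  findings$policy <- vapply(findings$rule_id, function(id)
    rule_by_id[[id]]$remediation, character(1))

  # row-level removals first, cell edits after; precedence for cell edits
  pol_order <- c(reload_dedupe = 1, verify_date = 2, drop_record = 3,
                 exclude_invalid = 4, reindex_fk = 5, mark_na = 6,
                 flag_only = 7)
  findings <- findings[order(pol_order[findings$policy]), , drop = FALSE]
  edited <- character(0)  # "table\rkey\relement" cells already handled

  for (i in seq_len(nrow(findings))) {
    f <- findings[i, ]
    tb <- store$tables[[f$table]]
    key_col <- table_key_column(store, f$table)
    if (f$policy == "flag_only") {
      note("flag_only", f$table, f$row_key, f$element, "left unresolved")
      next
    }
    if (f$policy == "reload_dedupe") {
      dup <- duplicated(tb[[key_col]])
      if (any(dup)) {
        store$tables[[f$table]] <- tb[!dup, , drop = FALSE]
        rownames(store$tables[[f$table]]) <- NULL
      }
      note("reload_dedupe", f$table, f$row_key, NA, "table deduplicated on primary key")
      next
    }
    if (f$policy == "verify_date") {
      rule <- rule_by_id[[f$rule_id]]
      person <- store$tables[["person"]]
      if (!is.null(reference) && nrow(reference) > 0) {
        m <- match(person$person_id, reference$patient_id)
        fixed <- !is.na(m)
        person$death_date[fixed] <- reference$death_date[m[fixed]]
        store$tables[["person"]] <- person
      }
      # still conflicting after verification -> the event record is wrong
      tb <- store$tables[[f$table]]
      row <- which(tb[[key_col]] == f$row_key)
      if (length(row) > 0) {
        death <- store$tables[["person"]]$death_date[
          match(tb[[rule$person_column %||% "person_id"]][row[1]],
                store$tables[["person"]]$person_id)]
        ev <- parse_iso_date(tb[[f$element]][row[1]])
        dd <- parse_iso_date(death)
        if (!is.na(ev) && !is.na(dd) && ev > dd) {
          store$tables[[f$table]] <- tb[-row, , drop = FALSE]
          rownames(store$tables[[f$table]]) <- NULL
          note("verify_date", f$table, f$row_key, f$element,
               "death date verified; conflicting event record removed")
        } else {
          note("verify_date", f$table, f$row_key, f$element,
               "death date corrected from reference")
        }
      }
      next
    }
    if (f$policy == "drop_record") {
      row <- which(tb[[key_col]] == f$row_key)
      if (length(row) > 0) {
        store$tables[[f$table]] <- tb[-row[1], , drop = FALSE]
        rownames(store$tables[[f$table]]) <- NULL
      }
      note("drop_record", f$table, f$row_key, f$element, "record removed")
      next
    }
    # cell policies: exclude_invalid / reindex_fk / mark_na
    cell_id <- paste(f$table, f$row_key, f$element, sep = "\r")
    if (cell_id %in% edited) next
    row <- which(tb[[key_col]] == f$row_key)
    if (length(row) > 0 && !is.na(f$element) && f$element %in% names(tb)) {
      tb[[f$element]][row[1]] <- "NA"
      store$tables[[f$table]] <- tb
      edited <- c(edited, cell_id)
      note(f$policy, f$table, f$row_key, f$element,
           "value excluded; cell marked NA")
    }
  }
  list(store = store,
       log = if (length(log)) do.call(rbind, log) else data.frame())
}

# ---------------------------------------------------------------------------
# Ledger oracle

#' Match quality findings against an injection ledger
#'
#' Joins the rule engine's findings with the ground-truth injection ledger on
#' the expected registry location (table, row key, element for cell defects;
#' table and key for row/pair defects) and the quality dimension. Returns
#' recall (ledger entries detected) and precision (findings explained by the
#' ledger).
#'
#' @param findings findings data.frame from [evaluate_quality()].
#' @param ledger ledger data.frame from [inject_errors()].
#' @return list with `recall`, `precision`, `matched`, `missed` (ledger rows
#'   not found) and `unexpected` (findings not in the ledger).
#' @export
match_ledger <- function(findings, ledger) {
  dim_map <- c(completeness = "completeness/-", validity_range = "validity/range",
               validity_format = "validity/format", timeline = "accuracy/timeline",
               business_rule = "accuracy/business_rule",
               uniqueness = "uniqueness/-", relationship = "consistency/relationship")
  lkey <- paste(ledger$registry_table, ledger$registry_key,
                ifelse(ledger$registry_element == "", "", ledger$registry_element),
                dim_map[ledger$dimension], sep = "\r")
  fel <- ifelse(is.na(findings$element), "", findings$element)
  # row/pair-level findings carry no element
  fel[findings$subdimension %in% c("business_rule", "-") &
        findings$dimension %in% c("accuracy", "uniqueness")] <- ""
  fkey <- paste(findings$table, findings$row_key, fel,
                paste(findings$dimension, findings$subdimension, sep = "/"),
                sep = "\r")
  matched <- intersect(lkey, fkey)
  list(recall = if (length(lkey) > 0) length(intersect(lkey, fkey)) / length(unique(lkey)) else 1,
       precision = if (length(fkey) > 0) length(fkey[fkey %in% lkey]) / length(fkey) else 1,
       matched = length(matched),
       missed = ledger[!(lkey %in% fkey), , drop = FALSE],
       unexpected = findings[!(fkey %in% lkey), , drop = FALSE])
}
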