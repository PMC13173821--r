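# ETL engine: cohort selection, the three automatable transform kinds
# (direct, multivariate, rule-based NLP), and registry construction against
# a table specification.

STUDY_WINDOW <- c("1990-01-01", "2023-12-31")

#' Select the study cohort from a CDW extract
#'
#' A patient is included when they have at least one C91.0 (ALL) diagnosis
#' dated within the study window (January 1990 – December 2023), are aged
#' under 18 at the first C91.0 diagnosis, and carry confirmatory evidence:
#' a bone-marrow blast percentage of at least 20, or an immunophenotype
#' parseable from flow-cytometry results (structured or narrative). Patients
#' with another malignancy code (C00–C97 excluding C91.0) dated before their
#' first C91.0 code are returned on a review-flag list rather than being
#' excluded automatically.
#'
#' @param extract a `source_extract` (needs `patients`, `diagnoses`, `labs`).
#' @param blast_threshold minimum blast percentage counting as confirmatory.
#' @param age_limit exclusive upper age bound in completed years at first
#'   C91.0 diagnosis.
#' @return list with `included` (character vector of patient ids),
#'   `review_flagged` (ids needing manual review for a possible earlier
#'   primary malignancy), and `exclusions` (data.frame `patient_id`,
#'   `reason`).
#' @export
select_patients <- function(extract, blast_threshold = 20, age_limit = 18) {
  stopifnot(inherits(extract, "source_extract"))
  for (rel in c("patients", "diagnoses", "labs"))
    if (is.null(extract[[rel]]) || nrow(extract[[rel]]) == 0 && rel != "labs")
      stop_input("select_patients: extract is missing the %s relation", rel)
  dx <- extract$diagnoses
  labs <- extract$labs
  pats <- extract$patients

  included <- character(0)
  flagged <- character(0)
  excl <- list()
  exclude <- function(pid, reason)
    excl[[length(excl) + 1L]] <<- data.frame(patient_id = pid, reason = reason,
                                             stringsAsFactors = FALSE)
  win_lo <- parse_iso_date(STUDY_WINDOW[1])
  win_hi <- parse_iso_date(STUDY_WINDOW[2])

  for (pid in pats$patient_id) {
    pd <- dx[dx$patient_id == pid, , drop = FALSE]
    all_dx <- pd[pd$icd10 == "C91.0", , drop = FALSE]
    dts <- parse_iso_date(all_dx$diag_date)
    in_window <- !is.na(dts) & dts >= win_lo & dts <= win_hi
    if (nrow(all_dx) == 0 || !any(in_window)) {
      exclude(pid, if (nrow(all_dx) == 0) "no C91.0 diagnosis"
              else "no C91.0 diagnosis within 1990-2023")
      next
    }
    first_dx <- format(min(dts[in_window]), "%Y-%m-%d")
    age <- age_at(pats$birth_date[match(pid, pats$patient_id)], first_dx)
    if (is.na(age) || age >= age_limit) {
      exclude(pid, sprintf("age %s at first C91.0 (limit < %d)",
                           ifelse(is.na(age), "unknown", age), age_limit))
      next
    }
    pl <- labs[labs$patient_id == pid, , drop = FALSE]
    blast_ok <- FALSE
    if (nrow(pl) > 0) {
      bl <- suppressWarnings(as.numeric(pl$value_num[pl$lab_type == "BLAST"]))
      blast_ok <- any(!is.na(bl) & bl >= blast_threshold)
    }
    immuno_ok <- FALSE
    if (!blast_ok && nrow(pl) > 0) {
      fl <- pl[pl$lab_type == "FLOW", , drop = FALSE]
      for (i in seq_len(nrow(fl))) {
        lin <- if (nzchar(fl$lineage[i] %||% "")) fl$lineage[i]
               else parse_immunophenotype(fl$value_text[i])$lineage
        if (lin %in% c("B cell", "T cell", "Mixed")) { immuno_ok <- TRUE; break }
      }
    }
    if (!blast_ok && !immuno_ok) {
      exclude(pid, "no confirmatory evidence (blast >= threshold or immunophenotype)")
      next
    }
    included <- c(included, pid)
    # earlier other-malignancy codes -> manual review flag
    other <- pd[pd$icd10 != "C91.0" & grepl("^C", pd$icd10), , drop = FALSE]
    if (nrow(other) > 0) {
      od <- parse_iso_date(other$diag_date)
      if (any(!is.na(od) & od < parse_iso_date(first_dx)))
        flagged <- c(flagged, pid)
    }
  }
  list(included = included, review_flagged = flagged,
       exclusions = if (length(excl)) do.call(rbind, excl) else
         data.frame(patient_id = character(0), reason = character(0)))
}

# ---------------------------------------------------------------------------
# Value transforms

# Named code-recoding transforms available to direct mappings.
DIRECT_TRANSFORMS <- list(
  identity = function(x) x,
  sex_code = function(x) c(M = "1", F = "2")[x],
  yn_flag = function(x) c(Y = "1", N = "0")[x]
)

#' Apply a direct mapping entry to a source relation
#'
#' One output value per source row: the referenced column, optionally
#' recoded through a named transform, then type-checked against the target
#' element's data type. Values that cannot be coerced (e.g. an impossible
#' calendar date for a `date` element) are not dropped: the raw value is kept
#' and the row is marked as a validity-format candidate for the quality
#' engine.
#'
#' @param entry list with `column` and optional `transform` (a name in the
#'   direct-transform registry).
#' @param source a source relation (data.frame).
#' @param element the target `data_element_spec` (or `NULL` to skip typing).
#' @return data.frame with `value` (character) and `format_issue` (logical).
#' @export
apply_direct <- function(entry, source, element = NULL) {
  if (nrow(source) == 0)
    return(data.frame(value = character(0), format_issue = logical(0)))
  col <- entry$column
  if (is.null(col) || !col %in% names(source))
    stop_input("direct mapping references unknown source column '%s'",
               col %||% "<missing>")
  vals <- as.character(source[[col]])
  tname <- entry$transform %||% "identity"
  trans <- DIRECT_TRANSFORMS[[tname]]
  if (is.null(trans)) stop_input("unknown direct transform '%s'", tname)
  out <- unname(trans(vals))
  out[is.na(out) & !is.na(vals) & nzchar(vals)] <-
    vals[is.na(out) & !is.na(vals) & nzchar(vals)]  # unrecognised codes kept raw
  issue <- rep(FALSE, length(out))
  if (!is.null(element)) {
    present <- !cell_missing(out)
    if (element$data_type == "date")
      issue <- present & !is_valid_iso_date(out)
    else if (element$data_type %in% c("integer", "decimal"))
      issue <- present & is.na(suppressWarnings(as.numeric(out)))
  }
  data.frame(value = ifelse(is.na(out), "", out), format_issue = issue,
             stringsAsFactors = FALSE)
}

#' Nearest qualifying laboratory value within a window
#'
#' The multivariate transform used for elements such as "WBC at diagnosis":
#' for one patient, the lab row of the requested type whose date falls in the
#' closed window `[anchor, anchor + window_days]` and lies nearest to the
#' anchor. Ties break deterministically: smallest absolute day distance, then
#' the earlier date, then stable input order.
#'
#' @param labs the labs relation.
#' @param patient_id patient identifier.
#' @param lab_type lab type code to consider.
#' @param anchor ISO anchor date.
#' @param window_days closed window length in days.
#' @return list with `value` (character, `""` when no qualifying row) and
#'   `source_row` (the contributing `lab_id`, or `NA`).
#' @export
nearest_lab_value <- function(labs, patient_id, lab_type, anchor,
                              window_days = 7) {
  cand <- labs[labs$patient_id == patient_id & labs$lab_type == lab_type, ,
               drop = FALSE]
  if (nrow(cand) == 0) return(list(value = "", source_row = NA_character_))
  a <- parse_iso_date(anchor)
  d <- parse_iso_date(cand$lab_date)
  delta <- as.numeric(d - a)
  ok <- !is.na(delta) & delta >= 0 & delta <= window_days
  if (!any(ok)) return(list(value = "", source_row = NA_character_))
  cand <- cand[ok, , drop = FALSE]
  delta <- delta[ok]
  ord <- order(abs(delta), delta, seq_along(delta), method = "radix")
  pick <- cand[ord[1], , drop = FALSE]
  list(value = as.character(pick$value_num), source_row = pick$lab_id)
}

MULTIVARIATE_TRANSFORMS <- c("nearest_lab_value")

# ---------------------------------------------------------------------------
# Registry construction

read_build_config <- function(mappings) {
  cfg <- read_config(mappings)
  if (is.null(cfg$mappings)) stop_input("mapping config has no 'mappings' block")
  cfg$mappings
}

#' Build the registry from a CDW extract
#'
#' Runs cohort selection, then populates one relation per schema table from
#' the mapping configuration: each table block names its source relation, an
#' optional row filter and reduction, and one mapping entry per registry
#' element (kinds `direct`, `multivariate`, `nlp`, `manual`, `unavailable`).
#' NLP entries parse the narrative column through the named parser and fall
#' back to the structured column for rows stored tabularly. Every automatable
#' element of the schema must have a mapping entry; a missing source relation
#' demotes that table's elements to unavailable with a warning rather than
#' failing the build. Row provenance (contributing source rows) is recorded
#' per table.
#'
#' @param extract a `source_extract`.
#' @param schema a `registry_schema`.
#' @param mappings mapping configuration: file path or parsed list with a
#'   `mappings` block.
#' @param parsers parser registry for NLP entries; see [default_parsers()].
#' @param cohort optional precomputed result of [select_patients()].
#' @return a `registry_store`: named list of registry relations (all-character
#'   data.frames), plus `schema`, `cohort`, `provenance` and
#'   `unavailable_elements`.
#' @export
build_registry <- function(extract, schema, mappings,
                           parsers = default_parsers(), cohort = NULL) {
  stopifnot(inherits(extract, "source_extract"),
            inherits(schema, "registry_schema"))
  cfg <- read_build_config(mappings)
  cfg_tables <- vapply(cfg, function(m) m$table, character(1))
  if (anyDuplicated(cfg_tables))
    stop_input("duplicate mapping block for table(s): %s",
               paste(unique(cfg_tables[duplicated(cfg_tables)]), collapse = ", "))
  # every automatable schema element must be mapped
  unmapped <- character(0)
  for (t in schema$tables) {
    blk <- cfg[[match(t$table_name, cfg_tables)]]
    mapped <- if (is.null(blk)) character(0) else
      vapply(blk$elements, function(e) e$element, character(1))
    for (e in t$elements)
      if (!e$element_id %in% mapped) unmapped <- c(unmapped, e$element_id)
  }
  if (length(unmapped) > 0)
    stop_input("unmapped registry element(s): %s",
               paste(unmapped, collapse = ", "))

  if (is.null(cohort)) cohort <- select_patients(extract)
  included <- cohort$included

  tables <- list()
  provenance <- list()
  unavailable <- character(0)

  for (t in schema$tables) {
    blk <- cfg[[match(t$table_name, cfg_tables)]]
    src_name <- blk$source
    src <- extract[[src_name]]
    el_ids <- vapply(blk$elements, function(e) e$element, character(1))
    kinds <- vapply(blk$elements, function(e) e$kind %||% "direct", character(1))
    if (is.null(src)) {
      warning(sprintf("source relation '%s' absent; elements of table '%s' reported unavailable",
                      src_name, t$table_name), call. = FALSE)
      unavailable <- c(unavailable,
                       el_ids[!kinds %in% c("manual", "unavailable")])
      tables[[t$table_name]] <- as.data.frame(
        stats::setNames(rep(list(character(0)), length(el_ids)), el_ids),
        stringsAsFactors = FALSE)
      next
    }
    unavailable <- c(unavailable, el_ids[kinds == "unavailable"])
    # cohort filter + declarative row filter
    pat_col <- blk$patient_column %||% "patient_id"
    rows <- src[src[[pat_col]] %in% included, , drop = FALSE]
    if (!is.null(blk$filter))
      rows <- rows[rows[[blk$filter$column]] == blk$filter$equals, ,
                   drop = FALSE]
    if (identical(blk$reduce, "first_by_date") && nrow(rows) > 0) {
      dcol <- blk$reduce_date
      rows <- order_by(rows, c(pat_col, dcol))
      rows <- rows[!duplicated(rows[[pat_col]]), , drop = FALSE]
    }
    out <- as.data.frame(
      stats::setNames(rep(list(rep("", nrow(rows))), length(el_ids)), el_ids),
      stringsAsFactors = FALSE)
    prov_rows <- rows[[blk$row_key]]
    nlp_cache <- new.env()
    for (j in seq_along(blk$elements)) {
      entry <- blk$elements[[j]]
      kind <- entry$kind %||% "direct"
      espec <- schema_element(schema, entry$element)
      if (kind == "direct") {
        dv <- apply_direct(entry, rows, espec)
        out[[j]] <- dv$value
      } else if (kind == "nlp") {
        pname <- entry$parser
        parser <- parsers[[pname]]
        if (is.null(parser))
          stop_input("nlp mapping for '%s' names unknown parser '%s'",
                     entry$element, pname %||% "<none>")
        vals <- character(nrow(rows))
        for (r in seq_len(nrow(rows))) {
          txt <- rows[[entry$column]][r]
          if (!cell_missing(txt)) {
            key <- paste0(pname, ":", r)
            parsed <- nlp_cache[[key]]
            if (is.null(parsed)) {
              parsed <- parser(txt)
              nlp_cache[[key]] <- parsed
            }
            v <- parsed[[entry$field]]
            vals[r] <- if (is.null(v) || is.na(v)) "" else as.character(v)
          } else if (!is.null(entry$fallback_column)) {
            fb <- rows[[entry$fallback_column]][r]
            vals[r] <- if (cell_missing(fb)) "" else
              structured_field_value(entry$field, fb)
          }
        }
        out[[j]] <- vals
      } else if (kind == "multivariate") {
        tname <- entry$transform
        if (is.null(tname) || !tname %in% MULTIVARIATE_TRANSFORMS)
          stop_input("multivariate mapping for '%s' names unknown transform '%s'",
                     entry$element, tname %||% "<none>")
        p <- entry$params
        vals <- character(nrow(rows))
        mv_prov <- character(nrow(rows))
        for (r in seq_len(nrow(rows))) {
          res <- nearest_lab_value(extract$labs, rows[[pat_col]][r],
                                   p$lab_type, rows[[p$anchor_column]][r],
                                   p$window_days %||% 7)
          vals[r] <- res$value
          mv_prov[r] <- res$source_row %||% NA_character_
        }
        out[[j]] <- vals
      } else {
        # manual / unavailable: schema column kept, left empty
        out[[j]] <- rep("", nrow(rows))
      }
    }
    tables[[t$table_name]] <- out
    if (is.null(blk$row_key) || !blk$row_key %in% names(rows))
      stop_input("mapping block for '%s': row_key must name a source column",
                 t$table_name)
    provenance[[t$table_name]] <- data.frame(
      registry_key = if (nrow(out) > 0) out[[t$primary_key[1]]] else character(0),
      source_relation = rep(src_name, nrow(out)),
      source_row = rows[[blk$row_key]],
      stringsAsFactors = FALSE)
  }
  structure(list(tables = tables, schema = schema, cohort = cohort,
                 provenance = provenance,
                 unavailable_elements = unique(unavailable),
                 extract_provenance = extract$provenance),
            class = "registry_store")
}

# Map a structured fallback column value onto an NLP-extracted field. Used
# when a dialect stores a result tabularly: the discrete value already is the
# target field (chromosome counts additionally get a ploidy class).
structured_field_value <- function(field, value) {
  if (field == "ploidy_class") {
    cnt <- suppressWarnings(as.integer(value))
    if (is.na(cnt)) return("")
    th <- default_ploidy_thresholds()
    return(if (cnt < th$hypodiploid_below) "hypodiploid"
           else if (cnt > th$hyperdiploid_above) "hyperdiploid"
           else "normal_range")
  }
  as.character(value)
}

#' @export
print.registry_store <- function(x, ...) {
  cat(sprintf("Registry store: %d tables, %d patients in cohort\n",
              length(x$tables), length(x$cohort$included)))
  for (nm in names(x$tables))
    cat(sprintf("  %-22s %5d rows\n", nm, nrow(x$tables[[nm]])))
  if (length(x$unavailable_elements) > 0)
    cat(sprintf("  unavailable elements: %s\n",
                paste(x$unavailable_elements, collapse = ", ")))
  invisible(x)
}

#' Write registry tables to CSV
#'
#' @param store a `registry_store`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_registry <- function(store, dir) {
  stopifnot(inherits(store, "registry_store"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(store$tables))
    utils::write.csv(store$tables[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  prov <- lapply(store$provenance, function(p) p)
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
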