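# Rule-based parsing of narrative laboratory reports into discrete registry
# variables: interphase FISH ("nuc ish") probe copy numbers, karyotype
# chromosome counts with ploidy classification, and flow-cytometry
# immunophenotype. Deliberately regular-expression based: the report fields
# are semi-structured, and deterministic rules keep every extraction
# auditable (no statistical NLP anywhere in the package).

#' Parse interphase FISH results in ISCN 'nuc ish' notation
#'
#' Each `nuc ish(...)` clause lists probe-wise signal counts, e.g.
#' `"nuc ish(CDKN2Ax0,D9Z5 x 2)(170/300)"`. Every `<SYMBOL>x<INT>` token
#' yields one finding; an optional trailing `(a/b)` fraction is attached to
#' all findings of the clause as abnormal-cells / cells-scored. Copy number
#' 0 or 1 is called a deletion, 2 normal, greater than 2 a gain. The parser
#' is total: text without any parsable clause yields a single indeterminate
#' finding retaining the raw text, and no content ever raises an error.
#' The multiplication glyph may be ASCII `x` or `×`, with arbitrary
#' internal spacing.
#'
#' @param text a single report string (`NA` is treated as unparseable and
#'   yields an indeterminate finding; `NULL` is an error).
#' @return a data.frame of findings with columns `probe`, `copy_number`,
#'   `cells_abnormal`, `cells_scored`, `call`
#'   (`deletion`/`normal`/`gain`/`indeterminate`) and `raw`.
#' @examples
#' parse_fish("nuc ish(CDKN2Ax0,D9Z5 × 2)(170/300)")
#' @export
parse_fish <- function(text) {
  if (is.null(text)) stop_input("parse_fish: text must not be NULL")
  stopifnot(length(text) == 1)
  raw <- as.character(text)
  indeterminate <- data.frame(
    probe = NA_character_, copy_number = NA_integer_,
    cells_abnormal = NA_integer_, cells_scored = NA_integer_,
    call = "indeterminate", raw = raw, stringsAsFactors = FALSE)
  if (is.na(raw)) return(indeterminate)
  # Clause: "nuc ish ( ... )" with optional "(a/b)" fractions following.
  clause_re <- "nuc\\s*ish\\s*\\(([^()]*)\\)((?:\\s*\\(\\s*[0-9]+\\s*/\\s*[0-9]+\\s*\\))*)"
  m <- gregexpr(clause_re, raw, perl = TRUE, ignore.case = TRUE)[[1]]
  if (m[1] == -1) return(indeterminate)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  out <- list()
  for (i in seq_along(starts)) {
    clause <- substr(raw, starts[i], starts[i] + lens[i] - 1)
    body <- sub(clause_re, "\\1", clause, perl = TRUE, ignore.case = TRUE)
    tail <- sub(clause_re, "\\2", clause, perl = TRUE, ignore.case = TRUE)
    frac <- regmatches(tail, regexpr("([0-9]+)\\s*/\\s*([0-9]+)", tail))
    if (length(frac) == 1) {
      nums <- as.integer(strsplit(gsub("\\s", "", frac), "/")[[1]])
      ca <- nums[1]; cs <- nums[2]
      if (!is.na(ca) && !is.na(cs) && ca > cs) { ca <- NA_integer_; cs <- NA_integer_ }
    } else { ca <- NA_integer_; cs <- NA_integer_ }
    tokens <- strsplit(body, ",", fixed = TRUE)[[1]]
    tok_re <- "^\\s*([A-Za-z][A-Za-z0-9.\\-]*)\\s*[x×]\\s*([0-9]+)\\s*$"
    parsed <- grepl(tok_re, tokens, perl = TRUE)
    if (!any(parsed)) { out[[length(out) + 1]] <- indeterminate; next }
    for (tk in tokens[parsed]) {
      probe <- sub(tok_re, "\\1", tk, perl = TRUE)
      copies <- as.integer(sub(tok_re, "\\2", tk, perl = TRUE))
      out[[length(out) + 1]] <- data.frame(
        probe = probe, copy_number = copies,
        cells_abnormal = ca, cells_scored = cs,
        call = if (copies < 2) "deletion" else if (copies == 2) "normal" else "gain",
        raw = raw, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(indeterminate)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Default ploidy thresholds on the modal chromosome count
#'
#' Hypodiploid below 44, normal range 44–50, hyperdiploid above 50; the
#' common pediatric-ALL convention. Both bounds are configurable.
#'
#' @return named list with `hypodiploid_below` and `hyperdiploid_above`.
#' @export
default_ploidy_thresholds <- function() {
  list(hypodiploid_below = 44L, hyperdiploid_above = 50L)
}

#' Extract the chromosome count and ploidy class from a karyotype report
#'
#' The leading integer (or the first bound of an integer range such as
#' `"44-46"`) before the first `(` or `,` is taken as the modal chromosome
#' count, e.g. `"43(X, Y) ..."` or `"46,XX"`. The ploidy class follows from
#' the configured thresholds; text with no parsable count is classified
#' indeterminate. No full ISCN grammar is attempted (no derivatives,
#' breakpoints or clone structure) — only the count is extracted.
#'
#' @param text a single report string (`NULL` or `NA` is an error).
#' @param thresholds list as returned by [default_ploidy_thresholds()].
#' @return list with `chromosome_count` (integer or `NA`), `ploidy_class`
#'   (`hypodiploid`, `normal_range`, `hyperdiploid` or `indeterminate`) and
#'   `raw_span` (the matched count token, or `NA`).
#' @examples
#' parse_karyotype("55,XY,+4,+6,+10")
#' @export
parse_karyotype <- function(text, thresholds = default_ploidy_thresholds()) {
  if (is.null(text) || length(text) != 1 || is.na(text))
    stop_input("parse_karyotype: text must be a single non-NA string")
  lo <- as.integer(thresholds$hypodiploid_below)
  hi <- as.integer(thresholds$hyperdiploid_above)
  if (is.na(lo) || is.na(hi) || lo > hi)
    stop_input("parse_karyotype: thresholds must satisfy hypodiploid_below <= hyperdiploid_above")
  raw <- as.character(text)
  re <- "^\\s*([0-9]+)(\\s*[-~]\\s*[0-9]+)?\\s*[(,]"
  m <- regexpr(re, raw, perl = TRUE)
  if (m[1] == -1)
    return(list(chromosome_count = NA_integer_,
                ploidy_class = "indeterminate", raw_span = NA_character_))
  span <- regmatches(raw, m)
  count <- as.integer(sub(re, "\\1", span, perl = TRUE))
  cls <- if (count < lo) "hypodiploid"
         else if (count > hi) "hyperdiploid"
         else "normal_range"
  list(chromosome_count = count, ploidy_class = cls,
       raw_span = trimws(sub("[(,]$", "", span)))
}

#' Default flow-cytometry marker lexicon
#'
#' Maps surface/cytoplasmic marker symbols to lymphoid lineage. B lineage:
#' CD19, CD10, CD20, CD22, CD79a, PAX5; T lineage: CD3, cCD3, CD7, CD2, CD5,
#' CD1a, CD4, CD8. Configurable; matching requires the marker to be reported
#' positive (`+`).
#'
#' @return named character vector, `marker -> "B"` or `"T"`.
#' @export
default_marker_lexicon <- function() {
  c(CD19 = "B", CD10 = "B", CD20 = "B", CD22 = "B", CD79a = "B", PAX5 = "B",
    CD3 = "T", cCD3 = "T", CD7 = "T", CD2 = "T", CD5 = "T", CD1a = "T",
    CD4 = "T", CD8 = "T")
}

#' Derive the immunophenotype lineage from a flow-cytometry report
#'
#' Scans the report for lexicon markers reported positive. Evidence from B
#' markers only yields `B cell`; T markers only, `T cell`; both, `Mixed`;
#' none, `unavailable`.
#'
#' @param text a single report string.
#' @param lexicon named character vector mapping marker symbols to `"B"` or
#'   `"T"`; see [default_marker_lexicon()].
#' @return list with `lineage` (`B cell`, `T cell`, `Mixed`, `unavailable`)
#'   and `evidence` (character vector of matched marker tokens).
#' @examples
#' parse_immunophenotype("Blasts positive for CD19+, CD10+")
#' @export
parse_immunophenotype <- function(text, lexicon = default_marker_lexicon()) {
  if (is.null(text) || length(text) != 1)
    stop_input("parse_immunophenotype: text must be a single string")
  if (length(lexicon) == 0) stop_input("parse_immunophenotype: empty lexicon")
  raw <- as.character(text)
  if (is.na(raw)) return(list(lineage = "unavailable", evidence = character(0)))
  hits <- character(0)
  for (marker in names(lexicon)) {
    # marker followed (possibly after spaces) by '+', not embedded in a
    # longer token (so CD3 does not match inside CD30).
    re <- paste0("(?<![A-Za-z0-9])", marker, "(?![A-Za-z0-9])\\s*\\+")
    if (grepl(re, raw, perl = TRUE)) hits <- c(hits, marker)
  }
  lineages <- unique(unname(lexicon[hits]))
  lineage <- if (length(lineages) == 0) "unavailable"
             else if (setequal(lineages, "B")) "B cell"
             else if (setequal(lineages, "T")) "T cell"
             else "Mixed"
  list(lineage = lineage, evidence = hits)
}

#' Default parser registry for NLP mapping entries
#'
#' Named list used by [build_registry()] to resolve `parser` names in mapping
#' configurations. Each parser takes a report string and returns a named list
#' of extracted fields.
#'
#' @return named list of parser functions (`fish`, `karyotype`, `flow`).
#' @export
default_parsers <- function() {
  list(
    fish = function(text) {
      f <- parse_fish(text)
      # First abnormal probe drives the per-row summary; normal-only reports
      # summarize as 'normal'.
      abn <- f[f$call %in% c("deletion", "gain"), , drop = FALSE]
      pick <- if (nrow(abn) > 0) abn[1, ] else f[1, ]
      list(probe = pick$probe, copy_number = pick$copy_number,
           cells_abnormal = pick$cells_abnormal,
           cells_scored = pick$cells_scored, call = pick$call)
    },
    karyotype = function(text) {
      k <- parse_karyotype(text)
      list(chromosome_count = k$chromosome_count,
           ploidy_class = k$ploidy_class)
    },
    flow = function(text) {
      p <- parse_immunophenotype(text)
      list(lineage = p$lineage,
           evidence = paste(p$evidence, collapse = ";"))
    }
  )
}
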