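# Automated-data-extraction (ADE) assessment: classify each registry element
# by how it can be extracted from a given CDW, and quantify the ADE
# proportion per table, per category and overall.

ADE_CLASSES <- c("direct", "multivariate", "nlp", "manual", "unavailable")
AUTOMATABLE_CLASSES <- c("direct", "multivariate", "nlp")

#' Load element-level extraction mappings
#'
#' Reads a flat mapping document (YAML/JSON, `mappings` block): one entry per
#' registry element with its transform kind and CDW source field references.
#' Invariants: `direct` entries reference exactly one source field;
#' `multivariate` entries reference at least two (or declare a one-to-many
#' relation); `nlp` entries name their parser; `unavailable` entries carry no
#' source references. Duplicate entries for one element are a configuration
#' error.
#'
#' @param mappings file path or parsed list.
#' @return list of mapping entries (element, kind, sources, parser).
#' @export
load_mappings <- function(mappings) {
  cfg <- read_config(mappings)
  if (is.null(cfg$mappings)) stop_input("mapping document has no 'mappings' block")
  out <- lapply(cfg$mappings, function(m) {
    if (is.null(m$element)) stop_input("mapping entry without 'element'")
    kind <- m$kind %||% "direct"
    if (!kind %in% ADE_CLASSES)
      stop_input("mapping for '%s': unknown kind '%s'", m$element, kind)
    srcs <- as.character(unlist(m$sources %||% character(0)))
    if (kind == "direct" && length(srcs) != 1)
      stop_input("mapping for '%s': direct entries need exactly one source",
                 m$element)
    if (kind == "multivariate" && length(srcs) < 2 && !isTRUE(m$one_to_many))
      stop_input("mapping for '%s': multivariate entries need >= 2 sources or one_to_many",
                 m$element)
    if (kind == "nlp" && is.null(m$parser))
      stop_input("mapping for '%s': nlp entries must name a parser", m$element)
    if (kind == "unavailable" && length(srcs) > 0)
      stop_input("mapping for '%s': unavailable entries carry no sources",
                 m$element)
    list(element = as.character(m$element), kind = kind, sources = srcs,
         parser = m$parser)
  })
  ids <- vapply(out, `[[`, character(1), "element")
  if (anyDuplicated(ids))
    stop_input("duplicate mapping(s) for element(s): %s",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out
}

#' Classify registry elements by extraction automatability
#'
#' Each element's class is its mapping's transform kind — except that a
#' mapping whose source fields are not all present in the institution's CDW
#' inventory is reclassified `unavailable` (the data cannot be extracted
#' there regardless of the declared transform). `automatable` is true for
#' the three automated kinds (direct, multivariate, nlp).
#'
#' @param mappings entries from [load_mappings()] (or a path/list).
#' @param cdw_inventory character vector of available source field names
#'   (or a path to / parsed config with a `fields` block).
#' @return data.frame with `element_id`, `ade_class`, `automatable`.
#' @export
classify_elements <- function(mappings, cdw_inventory) {
  if (is.character(mappings) ||
      (is.list(mappings) && !is.null(mappings$mappings)))
    mappings <- load_mappings(mappings)
  if (is.character(cdw_inventory) && length(cdw_inventory) == 1 &&
      file.exists(cdw_inventory)) {
    inv_cfg <- read_config(cdw_inventory)
    cdw_inventory <- as.character(unlist(inv_cfg$fields %||% inv_cfg))
  }
  cls <- vapply(mappings, function(m) {
    if (m$kind %in% c("manual", "unavailable")) return(m$kind)
    if (length(m$sources) > 0 && !all(m$sources %in% cdw_inventory))
      return("unavailable")
    m$kind
  }, character(1))
  data.frame(element_id = vapply(mappings, `[[`, character(1), "element"),
             ade_class = cls,
             automatable = cls %in% AUTOMATABLE_CLASSES,
             stringsAsFactors = FALSE)
}

#' ADE proportion
#'
#' The percentage of key data elements automatically extractable in a scope:
#' `100 * automated / total`. Reported with the raw ratio and the half-up
#' one-decimal display value.
#'
#' @param classifications data.frame from [classify_elements()].
#' @param schema a `registry_schema` (needed for table/category scopes).
#' @param scope `"overall"`, `"table"` or `"category"`.
#' @param which table or category name when scope is not overall.
#' @return list with `automated`, `total`, `percent` (raw) and `display`.
#' @examples
#' \dontrun{ade_proportion(cls, schema, scope = "table", which = "hsct_main")}
#' @export
ade_proportion <- function(classifications, schema = NULL,
                           scope = c("overall", "table", "category"),
                           which = NULL) {
  scope <- match.arg(scope)
  cls <- classifications
  if (scope != "overall") {
    if (is.null(schema)) stop_input("ade_proportion: schema required for scope '%s'", scope)
    inv <- element_inventory(schema)
    inv <- inv[inv$is_key_element, , drop = FALSE]
    cls <- merge(cls, inv[, c("element_id", "table", "category")],
                 by = "element_id")
    cls <- cls[cls[[scope]] == which, , drop = FALSE]
  }
  if (nrow(cls) == 0)
    stop_input("ade_proportion: empty scope%s",
               if (is.null(which)) "" else sprintf(" '%s'", which))
  automated <- sum(cls$automatable)
  total <- nrow(cls)
  pct <- 100 * automated / total
  list(automated = automated, total = total, percent = pct,
       display = round_half_up(pct, 1))
}

#' Tabulate ADE classes per table, category and overall
#'
#' Builds the full assessment matrix: per subcategory table and per category,
#' tallies of each extraction class, the automatable subtotal, and the ADE
#' proportion. Only key data elements enter the denominators.
#'
#' @param classifications data.frame from [classify_elements()].
#' @param schema a `registry_schema`.
#' @return an `ade_report`: list with `by_table`, `by_category` and `overall`
#'   data.frames.
#' @export
ade_report <- function(classifications, schema) {
  inv <- element_inventory(schema)
  inv <- inv[inv$is_key_element, , drop = FALSE]
  df <- merge(inv[, c("element_id", "table", "category", "subcategory")],
              classifications, by = "element_id")
  if (nrow(df) < nrow(inv))
    stop_input("ade_report: %d key element(s) lack a classification",
               nrow(inv) - nrow(df))
  tally <- function(rows, label_cols) {
    t <- table(factor(rows$ade_class, levels = ADE_CLASSES))
    auto <- sum(t[AUTOMATABLE_CLASSES])
    cbind(label_cols,
          data.frame(n = nrow(rows), direct = t[["direct"]],
                     multivariate = t[["multivariate"]], nlp = t[["nlp"]],
                     automatable = auto, manual = t[["manual"]],
                     unavailable = t[["unavailable"]],
                     not_automatable = t[["manual"]] + t[["unavailable"]],
                     ade_percent = 100 * auto / nrow(rows),
                     ade_display = round_half_up(100 * auto / nrow(rows), 1),
                     stringsAsFactors = FALSE))
  }
  by_table <- do.call(rbind, lapply(unique(df$table), function(tb)
    tally(df[df$table == tb, ],
          data.frame(table = tb,
                     category = df$category[df$table == tb][1],
                     subcategory = df$subcategory[df$table == tb][1],
                     stringsAsFactors = FALSE))))
  cats <- REGISTRY_CATEGORIES[REGISTRY_CATEGORIES %in% df$category]
  by_category <- do.call(rbind, lapply(cats, function(cc)
    tally(df[df$category == cc, ],
          data.frame(category = cc, stringsAsFactors = FALSE))))
  overall <- tally(df, data.frame(scope = "overall", stringsAsFactors = FALSE))
  rownames(by_table) <- rownames(by_category) <- rownames(overall) <- NULL
  structure(list(by_table = by_table, by_category = by_category,
                 overall = overall),
            class = "ade_report")
}

#' Share of one transform class among automatable elements
#'
#' @param classifications data.frame from [classify_elements()].
#' @param class one of `direct`, `multivariate`, `nlp`.
#' @return list with `count`, `automatable`, `percent`, `display` (half-up,
#'   one decimal).
#' @export
ade_class_share <- function(classifications, class) {
  stopifnot(class %in% AUTOMATABLE_CLASSES)
  auto <- sum(classifications$automatable)
  if (auto == 0) stop_input("ade_class_share: no automatable elements")
  cnt <- sum(classifications$ade_class == class)
  list(count = cnt, automatable = auto, percent = 100 * cnt / auto,
       display = round_half_up(100 * cnt / auto, 1))
}

#' @export
print.ade_report <- function(x, ...) {
  cat("ADE assessment\n")
  bc <- x$by_category
  for (i in seq_len(nrow(bc)))
    cat(sprintf("  %-10s %3d elements, %3d automatable (%.1f%%)\n",
                bc$category[i], bc$n[i], bc$automatable[i], bc$ade_display[i]))
  ov <- x$overall
  cat(sprintf("  OVERALL    %3d elements, %3d automatable (%.1f%%)\n",
              ov$n, ov$automatable, ov$ade_display))
  invisible(x)
}
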