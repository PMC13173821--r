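# Registry table specifications: categories, subcategory tables, element
# attributes (type, length, NOT NULL), primary and foreign keys.

REGISTRY_CATEGORIES <- c("Person", "Diagnosis", "Laboratory", "Drug",
                         "Surgery", "HSCT", "Visit")

ELEMENT_TYPES <- c("text", "integer", "decimal", "date", "code")

# Canonical subcategory -> category assignment for the packaged registry
# inventory. Schemas may introduce further subcategories; when one of these
# names is used it must sit under its canonical category.
CANONICAL_SUBCATEGORIES <- c(
  "Person" = "Person",
  "ALL" = "Diagnosis", "Other diagnoses" = "Diagnosis",
  "Peripheral Blood" = "Laboratory", "Bone Marrow" = "Laboratory",
  "Flow Cytometry" = "Laboratory", "Chromosome" = "Laboratory",
  "Molgen" = "Laboratory", "FISH" = "Laboratory", "NGS" = "Laboratory",
  "Cerebrospinal Fluid" = "Laboratory", "Imaging" = "Laboratory",
  "Chemotherapy" = "Drug", "HSCT Drug" = "Drug", "Other Drugs" = "Drug",
  "ALL Surgery" = "Surgery", "Other Surgery" = "Surgery",
  "HSCT" = "HSCT", "GVHD" = "HSCT",
  "Visit" = "Visit"
)

#' Load and validate a registry table specification
#'
#' Reads a structured schema configuration (YAML or JSON) describing the
#' registry: one block per table with its category, subcategory, ordered data
#' elements (name, data type, maximum length, NOT NULL status, optional value
#' domain), a primary key, and foreign keys to other tables. All structural
#' invariants are checked: the seven-category vocabulary, canonical
#' subcategory/category consistency, uniqueness of element identifiers across
#' the schema, primary-key elements existing and NOT NULL, and every foreign
#' key resolving to a declared table's primary-key element.
#'
#' @param spec a file path to a `.yaml`/`.yml`/`.json` schema document, or an
#'   already-parsed list with the same structure.
#' @return an object of class `registry_schema`: a list with `version` and
#'   `tables` (named list of `table_spec` objects).
#' @examples
#' f <- system.file("extdata", "registry_schema.yaml", package = "allregistry")
#' sch <- load_schema(f)
#' sch
#' @export
load_schema <- function(spec) {
  doc <- read_config(spec)
  if (is.null(doc$tables) || length(doc$tables) == 0)
    stop_input("schema error: no tables defined")
  tables <- lapply(doc$tables, parse_table_spec)
  names(tables) <- vapply(tables, function(t) t$table_name, character(1))
  if (anyDuplicated(names(tables)))
    stop_input("schema error: duplicate table name(s): %s",
               paste(unique(names(tables)[duplicated(names(tables))]),
                     collapse = ", "))
  schema <- structure(
    list(version = as.character(doc$version %||% "1"), tables = tables),
    class = "registry_schema")
  validate_schema(schema)
  schema
}

read_config <- function(spec) {
  if (is.character(spec) && length(spec) == 1) {
    if (!file.exists(spec)) stop_input("config file not found: %s", spec)
    if (grepl("\\.json$", spec, ignore.case = TRUE))
      return(jsonlite::read_json(spec, simplifyVector = FALSE))
    return(yaml::read_yaml(spec))
  }
  if (is.list(spec)) return(spec)
  stop_input("config must be a file path or a parsed list")
}

parse_table_spec <- function(tb) {
  for (f in c("table", "category", "elements"))
    if (is.null(tb[[f]]))
      stop_input("parse error in table '%s': missing field '%s'",
                 tb$table %||% "<unnamed>", f)
  elements <- lapply(tb$elements, parse_element_spec,
                     table = tb$table, category = tb$category,
                     subcategory = tb$subcategory %||% tb$table)
  structure(list(
    table_name = as.character(tb$table),
    category = as.character(tb$category),
    subcategory = as.character(tb$subcategory %||% tb$table),
    elements = elements,
    primary_key = as.character(unlist(tb$primary_key %||% character(0))),
    foreign_keys = lapply(tb$foreign_keys %||% list(), function(fk) {
      for (f in c("element", "ref_table", "ref_element"))
        if (is.null(fk[[f]]))
          stop_input("parse error in table '%s': foreign key missing '%s'",
                     tb$table, f)
      list(element = as.character(fk$element),
           ref_table = as.character(fk$ref_table),
           ref_element = as.character(fk$ref_element))
    })
  ), class = "table_spec")
}

parse_element_spec <- function(el, table, category, subcategory) {
  if (is.null(el$id))
    stop_input("parse error in table '%s': element without 'id'", table)
  if (is.null(el$type))
    stop_input("parse error: element '%s' has no 'type'", el$id)
  if (!el$type %in% ELEMENT_TYPES)
    stop_input("parse error: element '%s' has unknown type '%s'",
               el$id, el$type)
  dom <- el$domain
  if (!is.null(dom)) {
    if (!is.null(dom$min) || !is.null(dom$max))
      dom <- list(kind = "range",
                  min = as.numeric(dom$min %||% -Inf),
                  max = as.numeric(dom$max %||% Inf))
    else dom <- list(kind = "codes", codes = as.character(unlist(dom)))
  }
  structure(list(
    element_id = as.character(el$id),
    name = as.character(el$name %||% el$id),
    category = as.character(category),
    subcategory = as.character(subcategory),
    data_type = as.character(el$type),
    max_length = if (is.null(el$max_length)) Inf else as.numeric(el$max_length),
    not_null = isTRUE(el$not_null),
    value_domain = dom,
    is_key_element = if (is.null(el$key_element)) TRUE else isTRUE(el$key_element)
  ), class = "data_element_spec")
}

validate_schema <- function(schema) {
  inv <- element_inventory(schema)
  if (anyDuplicated(inv$element_id))
    stop_input("schema error: duplicate element id(s): %s",
               paste(unique(inv$element_id[duplicated(inv$element_id)]),
                     collapse = ", "))
  for (t in schema$tables) {
    if (!t$category %in% REGISTRY_CATEGORIES)
      stop_input("schema error: table '%s' has unknown category '%s'",
                 t$table_name, t$category)
    canon <- CANONICAL_SUBCATEGORIES[t$subcategory]
    if (!is.na(canon) && canon != t$category)
      stop_input(
        "schema error: subcategory '%s' belongs to category '%s', not '%s'",
        t$subcategory, canon, t$category)
    ids <- vapply(t$elements, function(e) e$element_id, character(1))
    if (length(t$primary_key) == 0)
      stop_input("schema error: table '%s' has no primary key", t$table_name)
    for (pk in t$primary_key) {
      if (!pk %in% ids)
        stop_input("schema error: primary key '%s' not an element of '%s'",
                   pk, t$table_name)
      if (!t$elements[[match(pk, ids)]]$not_null)
        stop_input("schema error: primary key '%s' of '%s' must be NOT NULL",
                   pk, t$table_name)
    }
    for (fk in t$foreign_keys) {
      if (!fk$element %in% ids)
        stop_input("schema error: FK element '%s' not in table '%s'",
                   fk$element, t$table_name)
      ref <- schema$tables[[fk$ref_table]]
      if (is.null(ref))
        stop_input("schema error: FK %s.%s references undeclared table '%s'",
                   t$table_name, fk$element, fk$ref_table)
      if (!fk$ref_element %in% ref$primary_key)
        stop_input(
          "schema error: FK %s.%s references '%s.%s' which is not a primary-key element",
          t$table_name, fk$element, fk$ref_table, fk$ref_element)
    }
  }
  invisible(schema)
}

#' Flat inventory of registry data elements
#'
#' Flattens a validated schema into one row per data element, in stable table
#' and declaration order. The number of rows equals the sum of per-table
#' element counts; `is_key_element` marks elements counting toward ADE
#' denominators.
#'
#' @param schema a `registry_schema`.
#' @return a data.frame with columns `element_id`, `name`, `table`,
#'   `category`, `subcategory`, `data_type`, `max_length`, `not_null`,
#'   `is_key_element`.
#' @export
element_inventory <- function(schema) {
  stopifnot(inherits(schema, "registry_schema"))
  rows <- lapply(schema$tables, function(t) {
    data.frame(
      element_id = vapply(t$elements, `[[`, character(1), "element_id"),
      name = vapply(t$elements, `[[`, character(1), "name"),
      table = t$table_name,
      category = t$category,
      subcategory = t$subcategory,
      data_type = vapply(t$elements, `[[`, character(1), "data_type"),
      max_length = vapply(t$elements, `[[`, numeric(1), "max_length"),
      not_null = vapply(t$elements, `[[`, logical(1), "not_null"),
      is_key_element = vapply(t$elements, `[[`, logical(1), "is_key_element"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialize a registry schema
#'
#' Writes the normalized schema back to a structured document. The result of
#' `load_schema(schema_to_list(x))` is identical to `x` (round-trip
#' stability).
#'
#' @param schema a `registry_schema`.
#' @param path optional file path (`.json` or `.yaml`); when `NULL` the
#'   normalized list is returned invisibly.
#' @return the normalized list representation, invisibly.
#' @export
schema_to_list <- function(schema, path = NULL) {
  stopifnot(inherits(schema, "registry_schema"))
  doc <- list(
    version = schema$version,
    tables = unname(lapply(schema$tables, function(t) {
      list(
        table = t$table_name, category = t$category,
        subcategory = t$subcategory,
        primary_key = as.list(t$primary_key),
        foreign_keys = t$foreign_keys,
        elements = lapply(t$elements, function(e) {
          el <- list(id = e$element_id, name = e$name, type = e$data_type,
                     not_null = e$not_null, key_element = e$is_key_element)
          if (is.finite(e$max_length)) el$max_length <- e$max_length
          if (!is.null(e$value_domain)) {
            el$domain <- if (e$value_domain$kind == "range")
              list(min = e$value_domain$min, max = e$value_domain$max)
            else as.list(e$value_domain$codes)
          }
          el
        }))
    })))
  if (!is.null(path)) {
    if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
    else yaml::write_yaml(doc, path)
  }
  invisible(doc)
}

# Element spec lookup by id (NULL when absent).
schema_element <- function(schema, element_id) {
  for (t in schema$tables)
    for (e in t$elements)
      if (e$element_id == element_id) return(e)
  NULL
}

#' @export
print.registry_schema <- function(x, ...) {
  inv <- element_inventory(x)
  cat(sprintf("Registry schema v%s: %d tables, %d data elements\n",
              x$version, length(x$tables), nrow(inv)))
  tab <- table(factor(inv$category, levels = REGISTRY_CATEGORIES))
  for (cat_name in names(tab))
    cat(sprintf("  %-10s %3d elements\n", cat_name, tab[[cat_name]]))
  invisible(x)
}

#' @export
print.table_spec <- function(x, ...) {
  cat(sprintf("Table '%s' (%s / %s): %d elements; PK = %s\n",
              x$table_name, x$category, x$subcategory, length(x$elements),
              paste(x$primary_key, collapse = "+")))
  invisible(x)
}
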