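#' Load a medication catalog from TSV
#'
#' The medication catalog is the drug-level dataset that powers component
#' fill-in and the safety guardrails: for each drug it records the dose form,
#' strength, active ingredients, which components are required in a typical
#' direction, and default (preferred) values for some components, e.g. the
#' verb "chew" instead of "take" for a chewable tablet.
#'
#' Expected columns (UTF-8, header row mandatory): `drug_id`, `description`,
#' `dose_form`, `strength`, `active_ingredients` (semicolon-separated),
#' `required` (semicolon-separated component labels), `default_verb`,
#' `default_dose`, `default_route`, `default_frequency`, `default_aux`
#' (a default for the auxiliary indication).
#'
#' Rows with a blank `drug_id` or an unparseable `required` field are
#' dropped and counted (mirroring catalog cleanup that discards records with
#' missing or invalid identifiers); on duplicate `drug_id` the first row
#' wins and the conflict is reported. When an optional `ndc` column is
#' present, rows whose NDC is neither a 10-11 digit code nor a dashed
#' 4-5/3-4/1-2 segment code are dropped too.
#'
#' @param path Path to the catalog TSV.
#' @return An object of class `medic_catalog`: a named list of entries keyed
#'   by `drug_id`, with attributes `dropped` (row drop count) and `source`.
#' @examples
#' cat_path <- system.file("extdata", "catalog.tsv", package = "medic")
#' ctl <- load_catalog(cat_path)
#' length(ctl)
#' @export
load_catalog <- function(path) {
  if (!file.exists(path)) stop(sprintf("catalog file not found: %s", path), call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                          colClasses = "character")
  if (nrow(df) == 0L) stop("catalog file is empty", call. = FALSE)
  need <- c("drug_id", "description", "dose_form", "strength",
            "active_ingredients", "required")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop(sprintf("catalog header missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  default_cols <- c(verb = "default_verb", dose = "default_dose",
                    route = "default_route", frequency = "default_frequency",
                    `auxi-indic` = "default_aux")
  entries <- list()
  dropped <- 0L
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    if (is.na(row$drug_id) || !nzchar(trimws(row$drug_id))) {
      dropped <- dropped + 1L
      next
    }
    req <- split_semicolon(row$required)
    if (length(req) > 0L && !all(req %in% component_labels())) {
      dropped <- dropped + 1L
      next
    }
    if ("ndc" %in% names(df) && !is_valid_ndc(row$ndc)) {
      dropped <- dropped + 1L
      next
    }
    defaults <- list()
    for (lab in names(default_cols)) {
      col <- default_cols[[lab]]
      val <- if (col %in% names(df)) row[[col]] else NA_character_
      if (!is.na(val) && nzchar(trimws(val))) defaults[[lab]] <- trimws(val)
    }
    id <- trimws(row$drug_id)
    if (!is.null(entries[[id]])) {
      message(sprintf("catalog: duplicate drug_id '%s' at row %d; keeping first", id, i))
      next
    }
    entries[[id]] <- structure(
      list(drug_id = id,
           description = row$description,
           dose_form = tolower(trimws(row$dose_form)),
           strength = row$strength,
           active_ingredients = split_semicolon(row$active_ingredients),
           required = req,
           defaults = defaults),
      class = "catalog_entry")
  }
  if (length(entries) == 0L) stop("catalog contains no valid rows", call. = FALSE)
  structure(entries, class = "medic_catalog",
            dropped = dropped, source = normalizePath(path))
}

# 10-11 plain digits, or dashed 4-5/3-4/1-2 segments
is_valid_ndc <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(FALSE)
  grepl("^([0-9]{10,11}|[0-9]{4,5}-[0-9]{3,4}-[0-9]{1,2})$", trimws(x))
}

split_semicolon <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(character())
  out <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  out[nzchar(out)]
}

#' Look up a drug in the catalog
#'
#' @param catalog A `medic_catalog`.
#' @param drug_id Drug identifier.
#' @return The `catalog_entry`, or `NULL` when the id is absent (absence is
#'   an ordinary signal, not an error; the pipeline degrades gracefully).
#' @export
catalog_lookup <- function(catalog, drug_id) {
  if (is.null(drug_id) || is.na(drug_id)) return(NULL)
  catalog[[as.character(drug_id)]]
}

#' @export
print.medic_catalog <- function(x, ...) {
  cat(sprintf("<medic_catalog> %d drugs (%d rows dropped on load)\n",
              length(x), attr(x, "dropped")))
  invisible(x)
}

#' @export
print.catalog_entry <- function(x, ...) {
  cat(sprintf("<catalog_entry %s> %s [%s]\n  required: %s\n  defaults: %s\n",
              x$drug_id, x$description, x$dose_form,
              paste(x$required, collapse = ", "),
              paste(sprintf("%s=%s", names(x$defaults), unlist(x$defaults)),
                    collapse = ", ")))
  invisible(x)
}
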