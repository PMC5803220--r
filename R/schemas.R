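#' Dataset schemas used across the pipeline
#'
#' Four delimited-text (CSV, UTF-8) schemas connect the pipeline stages.
#' Booleans are serialized as 0/1; species labels are free strings
#' matched case-sensitively after trimming.
#'
#' * `feeding_trial`: `predator_species`, `prey_species`,
#'   `hours_post_feeding` (non-negative hours), `detected` (0/1).
#' * `field_survey_units`: `unit_id` (unique), `aphid_density`
#'   (aphids per 10 leaves, non-negative).
#' * `field_survey_larvae`: `larva_id`, `unit_id`, `predator_species`,
#'   `instar` (1-4), `detected_aphid` (0/1), `detected_heterospecific`
#'   (0/1).
#' * `lab_bioassay`: `ig_predator_species`, `prey_stage_class` (one of
#'   `immobile`, `small_larvae`, `similar_larvae`), `aphid_density`
#'   (aphids per arena, non-negative), `predation` (0/1).
#'
#' @return Character vector of schema names.
#' @export
#' @examples
#' igp_schemas()
igp_schemas <- function() {
  c("feeding_trial", "field_survey_units", "field_survey_larvae", "lab_bioassay")
}

stage_classes <- function() c("immobile", "small_larvae", "similar_larvae")

prey_kinds <- function() c("aphid", "heterospecific")

# Internal schema registry: column name -> semantic type.
schema_def <- function(schema) {
  switch(schema,
    feeding_trial = list(
      cols = c(
        predator_species = "character", prey_species = "character",
        hours_post_feeding = "numeric", detected = "logical"
      )
    ),
    field_survey_units = list(
      cols = c(unit_id = "character", aphid_density = "numeric")
    ),
    field_survey_larvae = list(
      cols = c(
        larva_id = "character", unit_id = "character",
        predator_species = "character", instar = "integer",
        detected_aphid = "logical", detected_heterospecific = "logical"
      )
    ),
    lab_bioassay = list(
      cols = c(
        ig_predator_species = "character", prey_stage_class = "character",
        aphid_density = "numeric", predation = "logical"
      )
    ),
    abort(paste0("unknown schema '", schema, "'"))
  )
}

coerce_column <- function(x, type) {
  x <- trimws(x)
  switch(type,
    character = x,
    numeric = suppressWarnings(as.numeric(x)),
    integer = suppressWarnings(as.integer(x)),
    logical = dplyr::case_match(
      toupper(x),
      c("0", "FALSE", "F") ~ FALSE,
      c("1", "TRUE", "T") ~ TRUE,
      .default = NA
    )
  )
}

# Row-level invariant checks; each returns a tibble(row, message).
schema_checks <- function(schema, tbl) {
  bad <- function(rows, msg) {
    if (length(rows) == 0) return(NULL)
    tibble::tibble(row = rows, message = paste0("row ", rows, ": ", msg))
  }
  out <- switch(schema,
    feeding_trial = list(
      bad(which(tbl$hours_post_feeding < 0), "hours_post_feeding must be >= 0"),
      bad(
        which(tbl$predator_species == tbl$prey_species),
        "predator_species equals prey_species"
      )
    ),
    field_survey_units = list(
      bad(which(tbl$aphid_density < 0), "aphid_density must be >= 0"),
      bad(
        which(duplicated(tbl$unit_id)),
        paste0("duplicate unit_id '", tbl$unit_id[duplicated(tbl$unit_id)], "'")
      )
    ),
    field_survey_larvae = list(
      bad(which(!tbl$instar %in% 1:4), "instar must be one of 1, 2, 3, 4")
    ),
    lab_bioassay = list(
      bad(
        which(!tbl$prey_stage_class %in% stage_classes()),
        paste0(
          "prey_stage_class must be one of ",
          paste(stage_classes(), collapse = ", ")
        )
      ),
      bad(which(tbl$aphid_density < 0), "aphid_density must be >= 0")
    )
  )
  dplyr::bind_rows(out)
}

#' Read a pipeline dataset from CSV
#'
#' Reads one of the four pipeline schemas (see [igp_schemas()]), coercing
#' columns to their semantic types and validating row-level invariants.
#' Row order is preserved. The returned tibble carries its schema name in
#' the `"igp_schema"` attribute, which [write_table()] uses.
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema One of `"feeding_trial"`, `"field_survey_units"`,
#'   `"field_survey_larvae"`, `"lab_bioassay"`.
#' @return A tibble with typed columns in schema order.
#' @export
load_table <- function(path, schema) {
  schema <- rlang::arg_match(schema, igp_schemas())
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  def <- schema_def(schema)
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    show_col_types = FALSE, progress = FALSE
  )
  missing <- setdiff(names(def$cols), names(raw))
  if (length(missing) > 0) {
    abort(paste0(
      "schema error in '", path, "': missing column(s) ",
      paste0("'", missing, "'", collapse = ", ")
    ))
  }
  if (nrow(raw) == 0) {
    abort(paste0("empty table: '", path, "' has a header but no rows"))
  }
  out <- purrr::imap(def$cols, function(type, col) {
    coerced <- coerce_column(raw[[col]], type)
    failed <- which(is.na(coerced) & !is.na(raw[[col]]) & trimws(raw[[col]]) != "")
    if (length(failed) > 0) {
      abort(paste0(
        "cannot coerce column '", col, "' to ", type, " at row(s) ",
        paste(head(failed, 5), collapse = ", "),
        if (length(failed) > 5) ", ..." else ""
      ))
    }
    na_rows <- which(is.na(coerced))
    if (length(na_rows) > 0) {
      abort(paste0(
        "missing value in column '", col, "' at row(s) ",
        paste(head(na_rows, 5), collapse = ", "),
        if (length(na_rows) > 5) ", ..." else ""
      ))
    }
    coerced
  })
  out <- tibble::as_tibble(out)
  problems <- schema_checks(schema, out)
  if (nrow(problems) > 0) {
    abort(paste0(
      "validation failed for '", path, "':\n",
      paste(head(problems$message, 10), collapse = "\n")
    ))
  }
  attr(out, "igp_schema") <- schema
  out
}

infer_schema <- function(records) {
  hits <- purrr::keep(igp_schemas(), function(s) {
    all(names(schema_def(s)$cols) %in% names(records))
  })
  if (length(hits) != 1) {
    abort("cannot infer schema from columns; pass `schema` explicitly")
  }
  hits
}

#' Write a pipeline dataset to CSV
#'
#' Inverse of [load_table()]: booleans are serialized as 0/1 so that a
#' write/load round trip reproduces the table field-for-field.
#'
#' @param records A tibble following one of the pipeline schemas.
#' @param path Output file path.
#' @param schema Schema name; defaults to the table's `"igp_schema"`
#'   attribute, or is inferred from the column names.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, schema = NULL) {
  schema <- schema %||% attr(records, "igp_schema") %||% infer_schema(records)
  schema <- rlang::arg_match(schema, igp_schemas())
  def <- schema_def(schema)
  missing <- setdiff(names(def$cols), names(records))
  if (length(missing) > 0) {
    abort(paste0(
      "records lack column(s) ", paste0("'", missing, "'", collapse = ", ")
    ))
  }
  out <- dplyr::select(
    tibble::as_tibble(records),
    dplyr::all_of(names(def$cols))
  )
  out <- dplyr::mutate(
    out,
    dplyr::across(dplyr::where(is.logical), as.integer)
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Cross-validate field-survey tables
#'
#' Checks the larva table against the sampling-unit table: larvae whose
#' `unit_id` is absent from the unit table (orphans), duplicated
#' `larva_id`s, and out-of-range instars. All issues are reported, never
#' raised; inputs are not modified. `n_dropped` counts larvae that a
#' downstream join would lose or that violate an invariant.
#'
#' @param units Tibble in the `field_survey_units` schema.
#' @param larvae Tibble in the `field_survey_larvae` schema.
#' @return A `igp_validation` list with `n_records`, `n_dropped` and
#'   `messages`.
#' @export
validate_field_survey <- function(units, larvae) {
  messages <- character()
  flagged <- logical(nrow(larvae))

  orphan <- which(!larvae$unit_id %in% units$unit_id)
  if (length(orphan) > 0) {
    messages <- c(messages, paste0(
      "larva '", larvae$larva_id[orphan], "' (row ", orphan,
      ") references unknown unit_id '", larvae$unit_id[orphan], "'"
    ))
    flagged[orphan] <- TRUE
  }

  dup_ids <- unique(larvae$larva_id[duplicated(larvae$larva_id)])
  for (id in dup_ids) {
    rows <- which(larvae$larva_id == id)
    messages <- c(messages, paste0(
      "duplicate larva_id '", id, "' at rows ",
      paste(rows, collapse = ", ")
    ))
    flagged[rows[-1]] <- TRUE
  }

  bad_instar <- which(!larvae$instar %in% 1:4)
  if (length(bad_instar) > 0) {
    messages <- c(messages, paste0(
      "larva '", larvae$larva_id[bad_instar], "' (row ", bad_instar,
      ") has instar ", larvae$instar[bad_instar], " outside 1-4"
    ))
    flagged[bad_instar] <- TRUE
  }

  structure(
    list(
      n_records = nrow(larvae),
      n_dropped = sum(flagged),
      messages = messages
    ),
    class = "igp_validation"
  )
}

#' @export
print.igp_validation <- function(x, ...) {
  cat("Field-survey validation:", x$n_records, "larva records,",
      x$n_dropped, "flagged\n")
  if (length(x$messages) > 0) {
    cat(paste0("  - ", x$messages, collapse = "\n"), "\n")
  } else {
    cat("  no issues found\n")
  }
  invisible(x)
}
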