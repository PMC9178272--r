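# Reading, validating and writing per-fly data tables in the released
# flat-table schema (one row per fly: three behavioral measures, their
# Levene-transformed counterparts, and experiment metadata).

#' Column names of the per-fly data table schema
#'
#' The canonical column set of the released per-fly measures table: the
#' fly identifier, the three behavioral measures (`handedness` = turn bias,
#' `numTurns`, `switchiness`), their Levene-transformed counterparts
#' (`lev_*`, group-wise absolute deviations used for variance modelling),
#' and the experiment metadata fields.
#'
#' @format Character vector of 21 column names.
#' @export
ymi_table1_columns <- c(
  "flyID", "handedness", "numTurns", "switchiness",
  "lev_handedness", "lev_numTurns", "lev_switchiness",
  "genotype", "expCond", "expTemp", "age", "experimenterID",
  "trayID", "boxID", "date", "arrayFormat", "mazeNum",
  "acquisition", "analysis", "sex", "eyeColor"
)

# Numeric columns of the schema; everything else is carried as character
# (including `date`, which is deliberately opaque: the original model
# excluded it because it renders the design rank deficient).
ymi_numeric_columns <- c(
  "flyID", "handedness", "numTurns", "switchiness",
  "lev_handedness", "lev_numTurns", "lev_switchiness", "expTemp", "age"
)

ymi_mandatory_columns <- c("handedness", "numTurns", "genotype")

ymi_categorical_columns <- c(
  "genotype", "expCond", "experimenterID", "trayID", "boxID", "date",
  "arrayFormat", "mazeNum", "acquisition", "analysis", "sex", "eyeColor"
)

#' Controlled vocabularies for sex and white-locus state
#'
#' `ymi_sex_levels` is the three-state sex encoding ("both" marks groups run
#' with mixed, unrecorded sex proportions). `ymi_eye_colors` encodes the
#' state of the *white* locus from wild type (`+/+`) through mini-white
#' rescue combinations to homozygous null (`-/-`); the exact legend strings
#' of the source data are not fully specified, so unknown codes are warned
#' about rather than rejected.
#'
#' @format Character vectors.
#' @export
ymi_sex_levels <- c("male", "female", "both")

#' @rdname ymi_sex_levels
#' @export
ymi_eye_colors <- c("+/+", "+/+mw.hs", "+/-", "-/+mw.hs", "-/-", "-/-;+mw.hs")

empty_cohort_records <- function() {
  cols <- lapply(ymi_table1_columns, function(cl) {
    if (cl == "flyID") integer(0)
    else if (cl %in% ymi_numeric_columns) numeric(0)
    else character(0)
  })
  names(cols) <- ymi_table1_columns
  tibble::as_tibble(cols)
}

#' Construct a cohort table
#'
#' Coerces a data frame of per-fly records to the canonical schema: missing
#' schema columns are added as missing values, schema columns come first
#' (extra columns are kept after them), and a provenance string is attached.
#'
#' @param records A data frame with (a subset of) the schema columns, or
#'   `NULL` for an empty table.
#' @param provenance Free-text descriptor of where the records came from.
#' @return A tibble of class `"cohort_table"` with a `provenance` attribute.
#' @export
#' @examples
#' cohort_table(tibble::tibble(
#'   flyID = 1:2, handedness = c(0.5, 0.25),
#'   numTurns = c(10, 4), genotype = "wt"
#' ))
cohort_table <- function(records = NULL, provenance = "unspecified") {
  if (is.null(records)) {
    records <- empty_cohort_records()
  }
  records <- tibble::as_tibble(records)
  for (cl in setdiff(ymi_table1_columns, names(records))) {
    records[[cl]] <- if (cl == "flyID") NA_integer_
      else if (cl %in% ymi_numeric_columns) NA_real_
      else NA_character_
  }
  extra <- setdiff(names(records), ymi_table1_columns)
  records <- records[, c(ymi_table1_columns, extra)]
  if (anyDuplicated(records$flyID[!is.na(records$flyID)]) > 0) {
    warning("duplicated flyID values in cohort table")
  }
  structure(records,
    provenance = provenance,
    class = c("cohort_table", class(records))
  )
}

#' Validate a cohort table against the schema invariants
#'
#' Checks each row against the schema's range and consistency invariants:
#' `handedness` in \[0, 1\]; `numTurns` a non-negative integer;
#' `switchiness` and `lev_*` non-negative; `handedness * numTurns` an
#' integer to within floating tolerance (a fraction of turns must be
#' realizable as a count); `sex` in the controlled vocabulary; unrecognized
#' `eyeColor` codes; duplicated `flyID`. Missing values are always allowed.
#'
#' @param table A `cohort_table` or coercible data frame.
#' @param strict What to do with rows that fail an invariant: `"warn"`
#'   (default) keeps them and emits a summary warning, `"drop"` removes
#'   them, `"error"` stops.
#' @param tol Floating tolerance for the handedness-times-turns
#'   integrality check.
#' @return The (possibly filtered) `cohort_table` with an `issues`
#'   attribute, a tibble with columns `row`, `column`, `problem`.
#' @export
validate_cohort <- function(table, strict = c("warn", "drop", "error"),
                            tol = 1e-6) {
  strict <- match.arg(strict)
  if (!inherits(table, "cohort_table")) {
    table <- cohort_table(table)
  }
  issues <- list()
  flag <- function(rows, column, problem) {
    if (length(rows)) {
      issues[[length(issues) + 1L]] <<-
        tibble(row = rows, column = column, problem = problem)
    }
  }

  h <- table$handedness
  n <- table$numTurns
  flag(which(!is.na(h) & (h < 0 | h > 1)), "handedness", "outside [0, 1]")
  flag(which(!is.na(n) & n < 0), "numTurns", "negative")
  flag(
    which(!is.na(n) & n >= 0 & abs(n - round(n)) > tol),
    "numTurns", "not an integer"
  )
  for (cl in c("switchiness", "lev_handedness", "lev_numTurns",
               "lev_switchiness")) {
    v <- table[[cl]]
    flag(which(!is.na(v) & v < 0), cl, "negative")
  }
  both <- which(!is.na(h) & !is.na(n) & n > 0 & h >= 0 & h <= 1)
  prod <- h[both] * n[both]
  flag(
    both[abs(prod - round(prod)) > tol * pmax(1, n[both])],
    "handedness", "handedness * numTurns is not an integer"
  )
  sx <- table$sex
  flag(
    which(!is.na(sx) & !(sx %in% ymi_sex_levels)),
    "sex", "not one of male/female/both"
  )
  ec <- table$eyeColor
  flag(
    which(!is.na(ec) & !(ec %in% ymi_eye_colors)),
    "eyeColor", "unrecognized white-locus code"
  )
  id <- table$flyID
  flag(
    which(!is.na(id) & duplicated(id)),
    "flyID", "duplicated"
  )

  issues <- if (length(issues)) {
    dplyr::bind_rows(issues)
  } else {
    tibble(row = integer(0), column = character(0), problem = character(0))
  }

  if (nrow(issues) > 0) {
    msg <- sprintf(
      "%d invariant violation(s) in %d row(s); first: row %d, %s %s",
      nrow(issues), length(unique(issues$row)),
      issues$row[1], issues$column[1], issues$problem[1]
    )
    if (strict == "error") stop(msg, call. = FALSE)
    if (strict == "warn") warning(msg, call. = FALSE)
    if (strict == "drop") {
      keep <- setdiff(seq_len(nrow(table)), unique(issues$row))
      prov <- attr(table, "provenance")
      table <- cohort_table(table[keep, , drop = FALSE], provenance = prov)
    }
  }
  attr(table, "issues") <- issues
  table
}

guess_format <- function(path, format) {
  if (format != "auto") return(format)
  if (grepl("\\.(parquet|pq)$", path, ignore.case = TRUE)) "parquet" else "csv"
}

#' Read a per-fly cohort table
#'
#' Reads a CSV or Parquet file whose header matches the released schema.
#' Header matching is case-insensitive; the mapping actually used is
#' recorded in the `column_mapping` attribute. Extra columns are kept.
#' Empty cells become missing values; numeric columns with unparseable
#' entries have those entries flagged as row-level issues.
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"csv"` or `"parquet"`. Parquet
#'   requires the `arrow` package.
#' @param strict Passed to [validate_cohort()].
#' @param quiet Suppress the column-mapping message.
#' @return A validated `cohort_table`.
#' @export
read_cohort <- function(path, format = c("auto", "csv", "parquet"),
                        strict = c("warn", "drop", "error"), quiet = FALSE) {
  format <- guess_format(path, match.arg(format))
  strict <- match.arg(strict)
  if (!file.exists(path)) {
    stop("file does not exist: ", path, call. = FALSE)
  }
  raw <- switch(format,
    csv = readr::read_csv(
      path,
      col_types = readr::cols(.default = readr::col_character()),
      na = c("", "NA"), progress = FALSE
    ),
    parquet = {
      if (!requireNamespace("arrow", quietly = TRUE)) {
        stop("reading parquet requires the 'arrow' package", call. = FALSE)
      }
      tab <- arrow::read_parquet(path)
      tab[] <- lapply(tab, as.character)
      tibble::as_tibble(tab)
    }
  )

  # Case-insensitive header resolution against the canonical names.
  mapping <- character(0)
  nm <- names(raw)
  for (canon in ymi_table1_columns) {
    hit <- which(tolower(nm) == tolower(canon))
    if (length(hit) >= 1) {
      mapping[nm[hit[1]]] <- canon
      names(raw)[hit[1]] <- canon
    }
  }
  missing_mand <- setdiff(ymi_mandatory_columns, names(raw))
  if (length(missing_mand)) {
    stop(
      "schema error: missing mandatory column(s): ",
      paste(missing_mand, collapse = ", "),
      call. = FALSE
    )
  }
  renamed <- mapping[names(mapping) != unname(mapping)]
  if (!quiet && length(renamed)) {
    message(
      "column name mapping applied: ",
      paste(names(renamed), "->", renamed, collapse = ", ")
    )
  }

  parse_issues <- list()
  for (cl in intersect(ymi_numeric_columns, names(raw))) {
    txt <- raw[[cl]]
    num <- suppressWarnings(as.numeric(txt))
    bad <- which(!is.na(txt) & is.na(num))
    if (length(bad)) {
      parse_issues[[cl]] <- tibble(
        row = bad, column = cl, problem = "unparseable numeric"
      )
    }
    raw[[cl]] <- if (cl == "flyID") {
      as.integer(round(num))
    } else {
      num
    }
  }
  if (length(parse_issues)) {
    pi <- dplyr::bind_rows(parse_issues)
    warning(
      sprintf("%d unparseable numeric cell(s) set to missing", nrow(pi)),
      call. = FALSE
    )
  }

  out <- cohort_table(raw, provenance = path)
  out <- validate_cohort(out, strict = strict)
  attr(out, "column_mapping") <- mapping
  out
}

#' Write a cohort table
#'
#' Writes CSV (RFC-4180, UTF-8, canonical header; missing values as empty
#' cells) or Parquet. Reading the file back with [read_cohort()] reproduces
#' the table field-for-field.
#'
#' @param table A `cohort_table` (or coercible data frame).
#' @param path Output path.
#' @param format `"auto"` (by extension), `"csv"` or `"parquet"`.
#' @return The path, invisibly.
#' @export
write_cohort <- function(table, path, format = c("auto", "csv", "parquet")) {
  format <- guess_format(path, match.arg(format))
  if (!inherits(table, "cohort_table")) table <- cohort_table(table)
  plain <- tibble::as_tibble(as.data.frame(table))
  switch(format,
    csv = readr::write_csv(plain, path, na = ""),
    parquet = {
      if (!requireNamespace("arrow", quietly = TRUE)) {
        stop("writing parquet requires the 'arrow' package", call. = FALSE)
      }
      arrow::write_parquet(plain, path)
    }
  )
  invisible(path)
}

#' Tabulate a metadata column
#'
#' Counts records per level of a categorical metadata column (missing
#' values counted under `NA`). Counts always sum to the number of records.
#'
#' @param table A `cohort_table`.
#' @param variable Name of a categorical schema column.
#' @return A tibble with columns `level` and `n`, sorted by decreasing `n`.
#' @export
summarize_metadata <- function(table, variable) {
  if (!is.character(variable) || length(variable) != 1 ||
      !(variable %in% ymi_categorical_columns)) {
    stop(
      "'variable' must be one of the categorical schema columns: ",
      paste(ymi_categorical_columns, collapse = ", "),
      call. = FALSE
    )
  }
  if (!variable %in% names(table)) {
    stop("unknown column: ", variable, call. = FALSE)
  }
  out <- tibble(level = table[[variable]]) |>
    dplyr::count(.data$level, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n))
  stopifnot(sum(out$n) == nrow(table))
  out
}

#' Read and write raw turn sequences
#'
#' Raw sequences travel as a long-format CSV with columns `flyID`,
#' `turn` (`"L"`/`"R"`) and optionally `time` (seconds, increasing within
#' a fly).
#'
#' @param path File path.
#' @return `read_turns()`: a named list of character vectors (one per fly,
#'   in file order); sequences with timestamps carry them in a `times`
#'   attribute.
#' @export
read_turns <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      flyID = readr::col_character(),
      turn = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
  if (!all(c("flyID", "turn") %in% names(raw))) {
    stop("turn file must have columns flyID and turn", call. = FALSE)
  }
  bad <- which(!raw$turn %in% c("L", "R"))
  if (length(bad)) {
    stop("turn labels must be 'L' or 'R' (first bad row: ", bad[1], ")",
      call. = FALSE)
  }
  ids <- unique(raw$flyID)
  out <- lapply(ids, function(id) {
    rows <- raw[raw$flyID == id, ]
    s <- rows$turn
    if ("time" %in% names(rows) && !all(is.na(rows$time))) {
      attr(s, "times") <- rows$time
    }
    s
  })
  names(out) <- ids
  out
}

#' @param seqs Named list of character turn vectors (see [read_turns()]).
#' @rdname read_turns
#' @export
write_turns <- function(seqs, path) {
  ids <- names(seqs) %||% as.character(seq_along(seqs))
  rows <- lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    tm <- attr(s, "times")
    tibble(
      flyID = rep(ids[i], length(s)),
      turn = as.character(s),
      time = if (is.null(tm)) rep(NA_real_, length(s)) else tm
    )
  })
  long <- dplyr::bind_rows(rows)
  if (all(is.na(long$time))) long$time <- NULL
  readr::write_csv(long, path, na = "")
  invisible(path)
}
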