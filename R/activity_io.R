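#' Read an experimental-activity or prediction table from CSV
#'
#' Reads a comma-separated table holding one experimental IC50 activity per
#' compound, optionally alongside the estimated activities of one or more
#' prediction systems (one column per system). Activities are kept in
#' nanomolar exactly as stored; no rounding or rescaling happens on ingest.
#'
#' @param path Path to a CSV file with a header row.
#' @param id_col Name of the compound-identifier column.
#' @param activity_col Name of the activity column (IC50, nM). Use `NULL` for
#'   a pure prediction table with no experimental column.
#' @param system_cols Character vector naming the prediction-system columns.
#'   The default `NULL` treats every numeric column other than `activity_col`
#'   as a system; non-numeric columns (e.g. a SMILES string or a set label)
#'   are carried through untouched.
#'
#' @return A tibble with columns `id`, `ic50_nM` (if present), one numeric
#'   column per prediction system, and any pass-through columns, in the
#'   file's row order. System column names are recorded in the
#'   `"systems"` attribute.
#'
#' @details Validation is strict: a column named in the schema that is absent
#'   raises a schema error naming it; a non-numeric or non-positive activity
#'   raises a parse error carrying the offending row index; duplicated
#'   compound identifiers raise an integrity error.
#'
#' @examples
#' path <- system.file("extdata", "table1.csv", package = "qsarfuse")
#' train <- read_activity_table(path)
#' attr(train, "systems")
#' @export
read_activity_table <- function(path, id_col = "id", activity_col = "ic50_nM",
                                system_cols = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "qsarfuse_io_error")
  }
  # base-R parsing: exact (correctly rounded) float round trips
  raw <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  need <- c(id_col, activity_col, system_cols)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "qsarfuse_schema_error")
  }
  out <- as_tibble(raw)
  if (nrow(out) == 0) {
    for (col in setdiff(names(out), id_col)) out[[col]] <- double()
  }
  names(out)[names(out) == id_col] <- "id"
  out$id <- as.character(out$id)
  if (any(is.na(out$id) | out$id == "")) {
    abort("empty compound identifier", class = "qsarfuse_parse_error")
  }
  if (anyDuplicated(out$id)) {
    dup <- unique(out$id[duplicated(out$id)])
    abort(paste0("duplicate compound id(s): ", paste(dup, collapse = ", ")),
          class = "qsarfuse_integrity_error")
  }
  if (!is.null(activity_col)) {
    names(out)[names(out) == activity_col] <- "ic50_nM"
    check_positive_column(out, "ic50_nM")
  }
  if (is.null(system_cols)) {
    num <- vapply(out, is.numeric, logical(1))
    system_cols <- setdiff(names(out)[num], c("id", "ic50_nM"))
  }
  for (s in system_cols) check_positive_column(out, s)
  front <- intersect(c("id", "ic50_nM"), names(out))
  out <- dplyr::relocate(out, all_of(front))
  structure(as_tibble(out), systems = system_cols)
}

# strict positivity check with the offending row index
check_positive_column <- function(data, col) {
  v <- data[[col]]
  if (!is.numeric(v)) {
    bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
    abort(paste0("column '", col, "' is not numeric (row ", bad, ")"),
          class = "qsarfuse_parse_error")
  }
  bad <- which(is.na(v) | v <= 0)
  if (length(bad)) {
    abort(paste0("non-positive or missing activity in column '", col,
                 "' at row ", bad[1]),
          class = "qsarfuse_parse_error")
  }
  invisible(TRUE)
}

#' Write an activity table to CSV
#'
#' Writes the table back with full stored precision so that a write/read
#' round trip reproduces identifiers, row order, and activities exactly.
#'
#' @param data A tibble as returned by [read_activity_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_activity_table <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' Read a virtual-screening results table from CSV
#'
#' A screening table holds, per candidate compound, the estimated IC50 from
#' the pharmacophore screen and the docking interaction energy.
#'
#' @param path Path to a CSV file.
#' @param id_col,est_col,energy_col Column names for compound id, estimated
#'   IC50 (nM, positive), and docking interaction energy (kcal/mol).
#' @return A tibble with columns `id`, `est_ic50_nM`, `energy_kcal_mol`.
#' @export
read_screening_table <- function(path, id_col = "id",
                                 est_col = "est_ic50_nM",
                                 energy_col = "energy_kcal_mol") {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "qsarfuse_io_error")
  }
  raw <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  need <- c(id_col, est_col, energy_col)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "qsarfuse_schema_error")
  }
  out <- tibble(
    id = as.character(raw[[id_col]]),
    est_ic50_nM = raw[[est_col]],
    energy_kcal_mol = raw[[energy_col]]
  )
  check_positive_column(out, "est_ic50_nM")
  if (!is.numeric(out$energy_kcal_mol)) {
    abort("energy column is not numeric", class = "qsarfuse_parse_error")
  }
  out
}

# md5 checksums locking the packaged transcriptions
.fixture_md5 <- c(
  table1 = "dd77676c792fc21adf4dec9e7b038d43",
  table2 = "6e629f09666ee06d39df9494c956cecb",
  table3 = "c21173e5f1c0e73c34d10ec8fc468dcd"
)

#' Load a packaged study table
#'
#' The package ships the three tables of the checkpoint kinase 2 (Chk2)
#' inhibitor study as plain CSV files:
#'
#' * `"table1"` — the 25 training-set inhibitors: experimental IC50 plus the
#'   estimated IC50 of the three pharmacophore-model systems
#'   `Best_train`, `Fast_train`, `Caesar_train`.
#' * `"table2"` — the 133 testing-set inhibitors: experimental IC50 plus the
#'   six crossed prediction systems `BB`, `BF`, `BC`, `FB`, `FF`, `FC`
#'   (train-algorithm x test-algorithm, B = Best, F = Fast, C = Caesar).
#' * `"table3"` — the 21 post-docking screening survivors: estimated IC50 and
#'   CDOCKER interaction energy (kcal/mol).
#'
#' @param name One of `"table1"`, `"table2"`, `"table3"`.
#' @param check Verify the file checksum against the locked transcription
#'   (default `TRUE`).
#' @return A tibble; for `table1`/`table2` the prediction-system column names
#'   are in the `"systems"` attribute.
#' @examples
#' train <- load_fixture("table1")
#' nrow(train)              # 25
#' screen <- load_fixture("table3")
#' @export
load_fixture <- function(name, check = TRUE) {
  if (length(name) != 1 || !name %in% names(.fixture_md5)) {
    abort(paste0("unknown fixture: ", paste(name, collapse = ", "),
                 " (expected one of table1, table2, table3)"),
          class = "qsarfuse_lookup_error")
  }
  path <- system.file("extdata", paste0(name, ".csv"), package = "qsarfuse",
                      mustWork = TRUE)
  if (isTRUE(check)) {
    got <- unname(tools::md5sum(path))
    if (!identical(got, unname(.fixture_md5[[name]]))) {
      abort(paste0("fixture ", name, " failed its checksum"),
            class = "qsarfuse_integrity_error")
    }
  }
  if (name == "table3") {
    read_screening_table(path)
  } else {
    read_activity_table(path)
  }
}

# prediction-system column names of a wide activity table
system_labels <- function(data, truth = "ic50_nM") {
  sys <- attr(data, "systems")
  if (!is.null(sys)) return(sys)
  num <- vapply(data, is.numeric, logical(1))
  setdiff(names(data)[num], c("id", truth))
}
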