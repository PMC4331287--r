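#' Measurement roles and their units
#'
#' The five morphometric variables handled by the package, with the fixed
#' unit convention: dorsal cranial length (DCL) in millimetres, snout-vent
#' length (SVL) and total length (TTL) in centimetres, body mass (BM) in
#' kilograms, and sustained bite force (BF) in newtons.
#'
#' @return Named character vector mapping role names to unit strings.
#' @export
#' @examples
#' measurement_roles()
measurement_roles <- function() {
  c(dcl = "mm", svl = "cm", ttl = "cm", bm = "kg", bf = "N")
}

role_unit <- function(role) unname(measurement_roles()[[role]])

check_role <- function(role) {
  if (!is.character(role) || length(role) != 1L ||
      !role %in% names(measurement_roles())) {
    abort_validation("unknown measurement role: ", paste(role, collapse = ", "),
                     " (valid roles: ", paste(names(measurement_roles()), collapse = ", "), ")")
  }
  role
}

#' Construct a calibration table of crocodilian measurements
#'
#' A calibration table holds one record per specimen (or per species mean)
#' with any subset of the five measurement roles present; absent measurements
#' are `NA`. Every present measurement must be strictly positive and finite,
#' every record must carry at least one measurement, and specimen identifiers
#' must be unique.
#'
#' @param specimen_id character vector of unique specimen labels.
#' @param species character vector of species labels (recycled if length 1).
#' @param dcl,svl,ttl,bm,bf numeric measurement vectors (`NA` = absent).
#'   Units follow [measurement_roles()].
#' @param source_label provenance text describing where the data come from.
#' @return A `calibration_table`, a `data.frame` subclass with columns
#'   `specimen_id`, `species` and the five roles.
#' @seealso [read_calibration()], [paired_view()]
#' @export
#' @examples
#' calibration_table(
#'   specimen_id = c("a", "b"), species = "Caiman latirostris",
#'   dcl = c(120, 250), svl = c(55, 130)
#' )
calibration_table <- function(specimen_id, species = "unknown",
                              dcl = NA_real_, svl = NA_real_, ttl = NA_real_,
                              bm = NA_real_, bf = NA_real_,
                              source_label = "unspecified") {
  n <- length(specimen_id)
  if (n == 0L) abort_validation("calibration table must be nonempty")
  df <- data.frame(
    specimen_id = as.character(specimen_id),
    species = rep_len(as.character(species), n),
    dcl = rep_len(as.numeric(dcl), n),
    svl = rep_len(as.numeric(svl), n),
    ttl = rep_len(as.numeric(ttl), n),
    bm = rep_len(as.numeric(bm), n),
    bf = rep_len(as.numeric(bf), n),
    stringsAsFactors = FALSE
  )
  attr(df, "source_label") <- source_label
  class(df) <- c("calibration_table", "data.frame")
  validate_calibration_table(df)
}

validate_calibration_table <- function(table) {
  roles <- names(measurement_roles())
  if (nrow(table) == 0L) abort_validation("calibration table must be nonempty")
  if (anyDuplicated(table$specimen_id)) {
    dup <- table$specimen_id[duplicated(table$specimen_id)][1L]
    abort_validation("duplicate specimen_id: '", dup, "'")
  }
  for (role in roles) {
    v <- table[[role]]
    bad <- which(!is.na(v) & (!is.finite(v) | v <= 0))
    if (length(bad)) {
      abort_validation("non-positive or non-finite ", role, " (", role_unit(role),
                       ") in row ", bad[1L], " (specimen '",
                       table$specimen_id[bad[1L]], "'): ", v[bad[1L]])
    }
  }
  present <- rowSums(!is.na(as.matrix(table[roles]))) > 0
  if (any(!present)) {
    abort_validation("row ", which(!present)[1L], " (specimen '",
                     table$specimen_id[which(!present)[1L]],
                     "') has no measurements")
  }
  table
}

#' Read a calibration table from a delimited text file
#'
#' Reads a comma-delimited UTF-8 file with a header row and maps its columns
#' onto measurement roles. Unmapped columns are ignored; empty cells become
#' absent measurements. Validation errors name the offending row and column.
#'
#' @param path path to a CSV file.
#' @param column_map named character vector mapping roles to file column
#'   names, e.g. `c(dcl = "DCL_mm", svl = "SVL_cm")`. May also map
#'   `specimen_id` and `species`; if not mapped, columns named `specimen_id`
#'   (or `id`) and `species` are used when present.
#' @param source_label provenance text; defaults to the file name.
#' @return A [calibration_table()].
#' @export
read_calibration <- function(path, column_map,
                             source_label = basename(path)) {
  if (!file.exists(path)) abort_validation("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  roles <- names(measurement_roles())
  if (anyDuplicated(names(column_map))) {
    abort_validation("column_map assigns a role more than once")
  }
  bad_roles <- setdiff(names(column_map), c(roles, "specimen_id", "species"))
  if (length(bad_roles)) {
    abort_validation("column_map contains unknown roles: ",
                     paste(bad_roles, collapse = ", "))
  }
  if (anyDuplicated(unname(column_map))) {
    abort_validation("column_map assigns one file column to multiple roles")
  }
  missing_cols <- setdiff(unname(column_map), names(raw))
  if (length(missing_cols)) {
    abort_validation("mapped columns absent from file: ",
                     paste(missing_cols, collapse = ", "))
  }

  id_col <- if ("specimen_id" %in% names(column_map)) column_map[["specimen_id"]]
            else intersect(c("specimen_id", "id"), names(raw))[1]
  if (is.na(id_col) || is.null(id_col)) {
    abort_validation("no specimen id column: map 'specimen_id' or provide an 'id' column")
  }
  sp_col <- if ("species" %in% names(column_map)) column_map[["species"]]
            else if ("species" %in% names(raw)) "species" else NA_character_

  parse_measure <- function(role) {
    if (!role %in% names(column_map)) return(rep(NA_real_, nrow(raw)))
    col <- column_map[[role]]
    txt <- trimws(raw[[col]])
    out <- suppressWarnings(as.numeric(txt))
    empty <- is.na(txt) | txt == ""
    out[empty] <- NA_real_
    bad <- which(!empty & is.na(out))
    if (length(bad)) {
      abort_validation("non-numeric value '", txt[bad[1L]], "' in column '",
                       col, "', row ", bad[1L])
    }
    out
  }
  vals <- lapply(roles, parse_measure)
  names(vals) <- roles

  calibration_table(
    specimen_id = raw[[id_col]],
    species = if (is.na(sp_col)) "unknown" else raw[[sp_col]],
    dcl = vals$dcl, svl = vals$svl, ttl = vals$ttl, bm = vals$bm, bf = vals$bf,
    source_label = source_label
  )
}

#' Write a calibration table to CSV
#'
#' Mirrors the input schema of [read_calibration()]: a header row with
#' `specimen_id`, `species` and one column per measurement role; absent
#' measurements become empty cells. Values are written at full precision so
#' a write-then-read round trip reproduces the table exactly.
#'
#' @param table a [calibration_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(table, path) {
  stopifnot(inherits(table, "calibration_table"))
  df <- as.data.frame(table)
  roles <- names(measurement_roles())
  for (role in roles) df[[role]] <- format(df[[role]], digits = 17, trim = TRUE)
  df[df == "NA"] <- ""
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Extract pairwise-complete (x, y) measurements
#'
#' Returns the records where both requested roles are present, in input
#' order, as a two-column data frame ready for regression fitting. Rows are
#' dropped only for the regression they cannot serve, since each allometric
#' relationship is fitted as a separate bivariate model.
#'
#' @param table a [calibration_table()].
#' @param x_role,y_role distinct measurement roles.
#' @return Data frame with columns `x`, `y` (and `specimen_id`), at most
#'   `nrow(table)` rows.
#' @export
#' @examples
#' tab <- calibration_table(c("a", "b", "c"), dcl = c(100, 200, 300),
#'                          svl = c(45, NA, 140))
#' paired_view(tab, "dcl", "svl")
paired_view <- function(table, x_role, y_role) {
  stopifnot(inherits(table, "calibration_table"))
  check_role(x_role)
  check_role(y_role)
  if (identical(x_role, y_role)) abort_validation("x_role and y_role must differ")
  keep <- !is.na(table[[x_role]]) & !is.na(table[[y_role]])
  if (sum(keep) < 3L) {
    abort_validation("too few complete (", x_role, ", ", y_role, ") pairs to fit: ",
                     sum(keep), " (need at least 3)")
  }
  data.frame(specimen_id = table$specimen_id[keep],
             x = table[[x_role]][keep], y = table[[y_role]][keep],
             stringsAsFactors = FALSE)
}

#' @export
print.calibration_table <- function(x, ...) {
  roles <- names(measurement_roles())
  n_present <- colSums(!is.na(as.matrix(as.data.frame(x)[roles])))
  cat("Calibration table: ", nrow(x), " records (",
      attr(x, "source_label"), ")\n", sep = "")
  cat("  measurements present: ",
      paste0(roles, "=", n_present, collapse = ", "), "\n", sep = "")
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("  ... and", nrow(x) - 6L, "more rows\n")
  invisible(x)
}
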