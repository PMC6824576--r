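#' @keywords internal
"_PACKAGE"

GROUP_LEVELS <- c("EOP", "LOP", "VALIDATION")

#' Construct and validate a cohort table
#'
#' A cohort table is the single input currency of every pipeline stage: a
#' dense numeric matrix of patients (rows) by immunologic parameters
#' (columns) together with a per-patient group label in
#' \code{c("EOP", "LOP", "VALIDATION")}.
#'
#' @param values Numeric matrix, one row per patient, one column per
#'   parameter.  Column names are the parameter names.
#' @param group_labels Character vector (or factor) of group labels, one per
#'   row, each one of \code{"EOP"}, \code{"LOP"}, \code{"VALIDATION"}.
#' @param patient_ids Unique patient identifiers; defaults to the row names
#'   of \code{values} or \code{P001, P002, ...}.
#'
#' @return An object of class \code{cohort_table}: a list with elements
#'   \code{values} (matrix with patient ids as row names), \code{group}
#'   (factor) and \code{parameters} (character).
#' @export
cohort_table <- function(values, group_labels, patient_ids = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  if (is.null(patient_ids)) {
    patient_ids <- rownames(values)
    if (is.null(patient_ids)) patient_ids <- sprintf("P%03d", seq_len(n))
  }
  patient_ids <- as.character(patient_ids)
  if (length(patient_ids) != n) {
    stop("number of patient ids (", length(patient_ids),
         ") does not match number of rows (", n, ")")
  }
  if (anyDuplicated(patient_ids)) {
    stop("duplicate patient ids: ",
         paste(unique(patient_ids[duplicated(patient_ids)]), collapse = ", "))
  }
  group_labels <- as.character(group_labels)
  if (length(group_labels) != n) {
    stop("number of group labels does not match number of rows")
  }
  bad <- setdiff(unique(group_labels), GROUP_LEVELS)
  if (length(bad)) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(GROUP_LEVELS, collapse = ", "), ")")
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("param%02d", seq_len(ncol(values)))
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate parameter names in cohort")
  }
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop("missing value at patient '", patient_ids[idx[1]], "', parameter '",
         colnames(values)[idx[2]], "'; complete-case input is required")
  }
  if (!all(is.finite(values))) stop("non-finite value in cohort matrix")
  rownames(values) <- patient_ids
  structure(
    list(values = values,
         group = factor(group_labels, levels = GROUP_LEVELS),
         parameters = colnames(values)),
    class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  tab <- table(droplevels(x$group))
  cat("<cohort_table> ", nrow(x$values), " patients x ",
      ncol(x$values), " parameters\n", sep = "")
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Number of patients / parameters in a cohort
#' @param cohort A \code{cohort_table}.
#' @return Integer count.
#' @export
n_patients <- function(cohort) nrow(cohort$values)

#' @rdname n_patients
#' @export
n_parameters <- function(cohort) ncol(cohort$values)

infer_format <- function(path, format = c("auto", "csv", "tsv", "xlsx")) {
  format <- match.arg(format)
  if (format != "auto") return(format)
  switch(tolower(tools::file_ext(path)),
         csv = "csv", tsv = "tsv", txt = "tsv",
         xlsx = "xlsx", xls = "xlsx",
         stop("cannot infer file format from extension of '", path,
              "'; pass format= explicitly"))
}

#' Read a cohort table from CSV, TSV or XLSX
#'
#' The expected layout is one header row, a first column of unique patient
#' ids, one numeric column per parameter, and a label column (default
#' \code{"group"}) holding the patient's cohort group.  Missing values,
#' duplicate ids, non-numeric cells and unknown group labels are hard
#' errors: no row is ever silently dropped or imputed.
#'
#' @param path File to read.
#' @param format One of \code{"auto"} (by extension), \code{"csv"},
#'   \code{"tsv"}, \code{"xlsx"}.
#' @param label_column Name of the column holding group labels.
#' @param id_column Name of the patient-id column; by default the first
#'   column of the file is used.
#' @param sheet Sheet (name or index) for XLSX input.
#' @param rename Optional named character vector mapping file column names
#'   to canonical parameter names (\code{c(file_name = "canonical")}).
#'
#' @return A validated \code{\link{cohort_table}}; parameter order is
#'   preserved from the file.
#' @export
read_cohort <- function(path, format = c("auto", "csv", "tsv", "xlsx"),
                        label_column = "group", id_column = NULL,
                        sheet = 1, rename = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- infer_format(path, format)
  if (format == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading XLSX requires the 'readxl' package")
    }
    df <- as.data.frame(readxl::read_excel(path, sheet = sheet),
                        stringsAsFactors = FALSE)
  } else {
    df <- utils::read.table(path, header = TRUE,
                            sep = if (format == "csv") "," else "\t",
                            quote = "\"", dec = ".", check.names = FALSE,
                            stringsAsFactors = FALSE, comment.char = "")
  }
  if (!nrow(df)) stop("file '", path, "' contains no data rows")
  if (is.null(id_column)) id_column <- names(df)[1]
  if (!id_column %in% names(df)) {
    stop("id column '", id_column, "' not found in ", path)
  }
  if (!label_column %in% names(df)) {
    stop("label column '", label_column, "' not found in ", path)
  }
  ids <- as.character(df[[id_column]])
  labels <- as.character(df[[label_column]])
  param_cols <- setdiff(names(df), c(id_column, label_column))
  vals <- matrix(NA_real_, nrow(df), length(param_cols),
                 dimnames = list(ids, param_cols))
  for (cn in param_cols) {
    col <- df[[cn]]
    if (is.character(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) & nzchar(trimws(col)))
      if (length(bad)) {
        stop("non-numeric value '", col[bad[1]], "' in column '", cn,
             "', row ", bad[1])
      }
      col <- num
    }
    if (anyNA(col)) {
      stop("missing value in column '", cn, "', row ", which(is.na(col))[1])
    }
    vals[, cn] <- as.numeric(col)
  }
  if (!is.null(rename)) {
    hit <- colnames(vals) %in% names(rename)
    colnames(vals)[hit] <- unname(rename[colnames(vals)[hit]])
  }
  cohort_table(vals, labels, ids)
}

#' Write a cohort table to CSV or TSV
#'
#' Writes the layout read by \code{\link{read_cohort}}: patient id first,
#' parameter columns, then the label column.  Values round-trip to at least
#' 1e-12 relative precision (15 significant digits).
#'
#' @param cohort A \code{cohort_table}.
#' @param path Output file.
#' @param format \code{"csv"} or \code{"tsv"} (default by extension).
#' @param label_column Name used for the group-label column.
#' @return Invisibly, \code{path}.
#' @export
write_cohort <- function(cohort, path, format = c("auto", "csv", "tsv"),
                         label_column = "group") {
  stopifnot(inherits(cohort, "cohort_table"))
  format <- infer_format(path, match.arg(format))
  if (format == "xlsx") stop("write_cohort supports csv and tsv output")
  df <- data.frame(patient_id = rownames(cohort$values),
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (cn in colnames(cohort$values)) {
    df[[cn]] <- format(cohort$values[, cn], digits = 15, trim = TRUE,
                       scientific = FALSE)
  }
  df[[label_column]] <- as.character(cohort$group)
  utils::write.table(df, path, sep = if (format == "csv") "," else "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Subset a cohort by group label
#'
#' @param cohort A \code{cohort_table}.
#' @param groups Non-empty character vector of group labels to keep.
#' @return A \code{cohort_table} with rows filtered (order preserved) and
#'   the parameter set unchanged.  An empty result is an error.
#' @export
subset_by_group <- function(cohort, groups) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (!length(groups)) stop("groups must be non-empty")
  bad <- setdiff(groups, GROUP_LEVELS)
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  keep <- cohort$group %in% groups
  if (!any(keep)) {
    stop("no patients in group(s) ", paste(groups, collapse = ", "))
  }
  cohort_table(cohort$values[keep, , drop = FALSE],
               as.character(cohort$group[keep]),
               rownames(cohort$values)[keep])
}
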