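#' Patient-by-drug sensitivity matrix
#'
#' Wraps a numeric matrix of drug-response values (rows = patients, columns =
#' drugs) together with the scale the values live on.  The scale decides the
#' optimization sense everywhere downstream: on `"log_ic50"` and `"ic50_star"`
#' scales smaller is better; on the `"benefit"` scale larger is better.
#'
#' @param values numeric matrix, patients in rows, drugs in columns. Dimnames
#'   are used as identifiers unless `patient_ids` / `drug_names` are given.
#' @param scale one of `"log_ic50"`, `"ic50_star"`, `"benefit"`. `"ic50_star"`
#'   asserts that every column has (observed-entry) mean zero.
#' @param patient_ids,drug_names character identifiers; must be unique.
#' @return a `sensitivity_matrix`: a numeric matrix with a `scale` attribute.
#' @seealso [biomarker_matrix()], [compute_ic50_star()], [to_benefit()]
#' @export
sensitivity_matrix <- function(values,
                               scale = c("log_ic50", "ic50_star", "benefit"),
                               patient_ids = rownames(values),
                               drug_names = colnames(values)) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("sensitivity matrix must have at least one patient and one drug",
         call. = FALSE)
  if (is.null(patient_ids)) patient_ids <- paste0("P", seq_len(nrow(values)))
  if (is.null(drug_names)) drug_names <- paste0("drug", seq_len(ncol(values)))
  .check_labels(patient_ids, nrow(values), "patient")
  .check_labels(drug_names, ncol(values), "drug")
  dimnames(values) <- list(patient_ids, drug_names)
  if (scale == "ic50_star") {
    mu <- colMeans(values, na.rm = TRUE)
    if (any(!is.finite(mu)))
      stop("all-missing drug column: ",
           paste(drug_names[!is.finite(mu)], collapse = ", "), call. = FALSE)
    if (any(abs(mu) > 1e-8))
      stop("scale 'ic50_star' requires zero column means; offending drugs: ",
           paste(drug_names[abs(mu) > 1e-8], collapse = ", "), call. = FALSE)
  }
  structure(values, scale = scale,
            class = c("sensitivity_matrix", "matrix", "array"))
}

#' Patient-by-marker biomarker matrix
#'
#' Rows are patients, columns are biomarkers (binary mutation calls or
#' continuous measurements such as expression).  A column is auto-detected as
#' binary iff all its values lie in \{0, 1\}; this can be overridden.
#' Missing biomarker values are rejected.
#'
#' @param values numeric matrix, patients in rows, markers in columns.
#' @param column_kind optional character vector (`"binary"`/`"continuous"`),
#'   one per column; default auto-detects.
#' @param patient_ids,marker_names character identifiers; must be unique.
#' @return a `biomarker_matrix`: numeric matrix with a `column_kind` attribute.
#' @export
biomarker_matrix <- function(values, column_kind = NULL,
                             patient_ids = rownames(values),
                             marker_names = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("biomarker matrix must have at least one patient and one marker",
         call. = FALSE)
  if (anyNA(values))
    stop("missing biomarker values are not supported", call. = FALSE)
  if (is.null(patient_ids)) patient_ids <- paste0("P", seq_len(nrow(values)))
  if (is.null(marker_names)) marker_names <- paste0("m", seq_len(ncol(values)))
  .check_labels(patient_ids, nrow(values), "patient")
  .check_labels(marker_names, ncol(values), "marker")
  dimnames(values) <- list(patient_ids, marker_names)
  detected <- ifelse(apply(values, 2L, function(x) all(x %in% c(0, 1))),
                     "binary", "continuous")
  if (is.null(column_kind)) {
    column_kind <- detected
  } else {
    column_kind <- rep_len(column_kind, ncol(values))
    if (!all(column_kind %in% c("binary", "continuous")))
      stop("column_kind entries must be 'binary' or 'continuous'",
           call. = FALSE)
    bad <- column_kind == "binary" & detected != "binary"
    if (any(bad))
      stop("columns declared binary but containing values outside {0,1}: ",
           paste(marker_names[bad], collapse = ", "), call. = FALSE)
  }
  names(column_kind) <- marker_names
  structure(values, column_kind = column_kind,
            class = c("biomarker_matrix", "matrix", "array"))
}

.check_labels <- function(x, n, what) {
  if (length(x) != n)
    stop(sprintf("%s labels (%d) do not match matrix dimension (%d)",
                 what, length(x), n), call. = FALSE)
  if (anyDuplicated(x))
    stop(sprintf("duplicate %s labels: %s", what,
                 paste(unique(x[duplicated(x)]), collapse = ", ")),
         call. = FALSE)
}

#' @export
print.sensitivity_matrix <- function(x, ...) {
  cat(sprintf("sensitivity_matrix: %d patients x %d drugs (scale: %s",
              nrow(x), ncol(x), attr(x, "scale")))
  cat(sprintf(", %d missing)\n", sum(is.na(x))))
  print(utils::head(unclass(x)[, seq_len(min(6L, ncol(x))), drop = FALSE]))
  invisible(x)
}

#' @export
print.biomarker_matrix <- function(x, ...) {
  kinds <- attr(x, "column_kind")
  cat(sprintf("biomarker_matrix: %d patients x %d markers (%d binary, %d continuous)\n",
              nrow(x), ncol(x), sum(kinds == "binary"),
              sum(kinds == "continuous")))
  print(utils::head(unclass(x)[, seq_len(min(6L, ncol(x))), drop = FALSE]))
  invisible(x)
}

#' @export
`[.sensitivity_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- unclass(x)[i, j, ..., drop = drop]
  if (is.matrix(out))
    out <- structure(out, scale = attr(x, "scale"),
                     class = c("sensitivity_matrix", "matrix", "array"))
  out
}

#' @export
`[.biomarker_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- unclass(x)[i, j, ..., drop = drop]
  if (is.matrix(out))
    out <- structure(out,
                     column_kind = attr(x, "column_kind")[colnames(out)],
                     class = c("biomarker_matrix", "matrix", "array"))
  out
}

#' Scale of a sensitivity matrix
#' @param Y a [sensitivity_matrix()].
#' @return the scale string.
#' @export
response_scale <- function(Y) {
  s <- attr(Y, "scale")
  if (is.null(s)) stop("not a sensitivity_matrix", call. = FALSE)
  s
}

# assert that Y (sensitivity) and X (biomarkers) describe the same patients,
# in the same order
check_aligned <- function(Y, X) {
  if (!identical(rownames(Y), rownames(X)))
    stop("patient identifiers of the sensitivity and biomarker matrices ",
         "do not align", call. = FALSE)
  invisible(TRUE)
}

#' Read a labelled matrix from delimited text
#'
#' Expects a header row of column labels and a first column of row labels
#' (patients in rows by default).  `"NA"` (any case) and empty cells are
#' treated as missing; missing values are only accepted for sensitivity
#' matrices.
#'
#' @param path file path (TSV by default; `sep = ","` for CSV; `.csv`
#'   extension auto-selects comma).
#' @param kind `"sensitivity"` or `"biomarker"`.
#' @param sep field separator; default inferred from the file extension.
#' @param transpose set `TRUE` if the file stores drugs/markers as rows.
#' @param scale scale flag attached when `kind = "sensitivity"`.
#' @param column_kind optional override passed to [biomarker_matrix()].
#' @return a [sensitivity_matrix()] or [biomarker_matrix()].
#' @export
read_matrix <- function(path, kind = c("sensitivity", "biomarker"),
                        sep = NULL, transpose = FALSE, scale = "log_ic50",
                        column_kind = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", na.strings = character(),
                           quote = "\"", comment.char = "")
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    stop("empty or label-only matrix in ", path, call. = FALSE)
  row_labels <- raw[[1L]]
  col_labels <- colnames(raw)[-1L]
  .check_labels(row_labels, nrow(raw), "row")
  .check_labels(col_labels, ncol(raw) - 1L, "column")
  body <- as.matrix(raw[, -1L, drop = FALSE])
  is_na <- toupper(trimws(body)) == "NA" | trimws(body) == ""
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- !is_na & is.na(num)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                 body[bad][1L], row_labels[idx[1L]], col_labels[idx[2L]]),
         call. = FALSE)
  }
  num[is_na] <- NA_real_
  dimnames(num) <- list(row_labels, col_labels)
  if (transpose) num <- t(num)
  if (kind == "sensitivity")
    sensitivity_matrix(num, scale = scale)
  else
    biomarker_matrix(num, column_kind = column_kind)
}

#' Write a labelled matrix to delimited text
#'
#' Inverse of [read_matrix()]: header row of column labels, first column of
#' row labels, `NA` for missing entries, full double precision.
#'
#' @param x a matrix (sensitivity or biomarker) with dimnames.
#' @param path output file path.
#' @param sep field separator (tab by default).
#' @param label name for the top-left header cell.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, sep = "\t", label = "id") {
  stopifnot(is.matrix(x))
  body <- format(unclass(x), digits = 17, trim = TRUE, scientific = FALSE)
  body[is.na(unclass(x))] <- "NA"
  df <- data.frame(rownames(x), body, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(label, colnames(x))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
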