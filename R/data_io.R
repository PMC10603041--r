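## Readers/writers for the plain-text formats the pipeline touches:
## TSV/CSV expression tables (genes x samples, first column = gene id),
## MatrixMarket coordinate triplets with *_rows.txt / *_cols.txt sidecars,
## MSigDB GMT gene sets, and clinical TSV tables.

#' Read an expression matrix from TSV, CSV or MatrixMarket triplet
#'
#' TSV/CSV files carry a header row of sample ids and a first column of gene
#' ids. An optional comment header line `#scale=<counts|logcpm|centered_logcpm>`
#' declares the value scale; the `scale` argument overrides it. For
#' `format = "mtx_triplet"`, `path` is the `.mtx` file and gene/sample ids are
#' read from sidecars `<stem>_rows.txt` and `<stem>_cols.txt` (one id per
#' line).
#'
#' @param path input file.
#' @param format one of `"tsv"`, `"csv"`, `"mtx_triplet"`; default guessed
#'   from the file extension.
#' @param scale value scale; overrides any declared metadata. Defaults to the
#'   file's `#scale=` header, else `"counts"`.
#' @param batch optional per-sample batch labels (recycled single value ok).
#' @param transpose set TRUE if the file stores samples as rows.
#' @return An [ExpressionMatrix-class].
#' @export
readExpression <- function(path, format = c("guess", "tsv", "csv", "mtx_triplet"),
                           scale = NULL, batch = NULL, transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "guess") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", mtx = "mtx_triplet", "tsv")
  }
  if (format == "mtx_triplet") {
    stem <- sub("\\.mtx$", "", path)
    rowsFile <- paste0(stem, "_rows.txt")
    colsFile <- paste0(stem, "_cols.txt")
    if (!file.exists(rowsFile) || !file.exists(colsFile))
      stop(sprintf("sidecar file(s) missing: need %s and %s", rowsFile, colsFile))
    m <- as.matrix(Matrix::readMM(path))
    rn <- readLines(rowsFile)
    cn <- readLines(colsFile)
    if (nrow(m) != length(rn) || ncol(m) != length(cn))
      stop("MTX dimensions do not match sidecar id counts")
    dimnames(m) <- list(rn, cn)
    declared <- NULL
  } else {
    sep <- if (format == "csv") "," else "\t"
    first <- readLines(path, n = 1L)
    declared <- if (startsWith(first, "#scale="))
      sub("^#scale=", "", trimws(first)) else NULL
    df <- read.delim(path, sep = sep, header = TRUE, comment.char = "#",
                     check.names = FALSE, colClasses = "character")
    ids <- df[[1L]]
    if (anyDuplicated(ids))
      stop(sprintf("duplicate gene id: '%s'", ids[duplicated(ids)][1]))
    body <- as.matrix(df[, -1L, drop = FALSE])
    suppressWarnings(num <- matrix(as.numeric(body), nrow = nrow(body)))
    if (anyNA(num)) {
      bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
      stop(sprintf("non-numeric value at gene '%s', sample '%s'",
                   ids[bad[1L]], colnames(body)[bad[2L]]))
    }
    dimnames(num) <- list(ids, colnames(body))
    m <- num
  }
  if (transpose) m <- t(m)
  if (is.null(scale)) scale <- if (!is.null(declared)) declared else "counts"
  if (is.null(batch)) batch <- rep("batch1", ncol(m))
  if (length(batch) == 1L) batch <- rep(batch, ncol(m))
  ExpressionMatrix(m, batch = batch, scale = scale)
}

#' Write an ExpressionMatrix to TSV with a scale header
#'
#' Writes a `#scale=` metadata line followed by a header row of sample ids
#' and one row per gene. [readExpression()] round-trips the result.
#'
#' @param x an [ExpressionMatrix-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(x, path) {
  stopifnot(is(x, "ExpressionMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#scale=%s", x@scale), con)
  df <- data.frame(gene_id = geneIds(x), x@values, check.names = FALSE)
  write.table(format(df, digits = 15, scientific = FALSE, trim = TRUE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard MSigDB dialect: one set per line, tab-separated
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. The description field is
#' discarded; duplicate members are dropped with a warning.
#'
#' @param path GMT file.
#' @return Named list of [GeneSet-class] objects (possibly empty).
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("GMT parse error at line %d: fewer than 3 fields", i))
    out[[f[1L]]] <- GeneSet(f[1L], f[-(1:2)])
  }
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets a [GeneSet-class] or list of them.
#' @param path output file.
#' @param description description field (second GMT column).
#' @return `path`, invisibly.
#' @export
writeGMT <- function(sets, path, description = "na") {
  if (is(sets, "GeneSet")) sets <- list(sets)
  lines <- vapply(sets, function(s)
    paste(c(s@name, description, s@genes), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

CLINICAL_COLS <- c("sample_id", "cohort", "os_time", "os_event")

#' Validate a clinical table
#'
#' Required columns: `sample_id`, `cohort`, `os_time` (non-negative),
#' `os_event` (0/1). Extra columns pass through untouched.
#'
#' @param df data.frame to check.
#' @return The validated data.frame with typed core columns.
#' @export
validateClinical <- function(df) {
  missing <- setdiff(CLINICAL_COLS, names(df))
  if (length(missing))
    stop(sprintf("clinical table missing column(s): %s",
                 paste(missing, collapse = ", ")))
  df$sample_id <- as.character(df$sample_id)
  df$cohort <- as.character(df$cohort)
  df$os_time <- as.numeric(df$os_time)
  df$os_event <- as.numeric(df$os_event)
  if (anyDuplicated(df$sample_id))
    stop(sprintf("duplicate sample_id: '%s'",
                 df$sample_id[duplicated(df$sample_id)][1]))
  if (anyNA(df$os_time) || any(df$os_time < 0))
    stop("os_time must be numeric and >= 0")
  if (anyNA(df$os_event) || !all(df$os_event %in% c(0, 1)))
    stop("os_event must be 0 or 1")
  df
}

#' Read a clinical TSV table
#'
#' @param path TSV with columns `sample_id`, `cohort`, `os_time`, `os_event`;
#'   extra columns preserved.
#' @return A validated data.frame.
#' @export
readClinical <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  validateClinical(read.delim(path, sep = "\t", header = TRUE,
                              check.names = FALSE))
}

#' Write a clinical table to TSV
#'
#' @param df clinical data.frame (validated before writing).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeClinical <- function(df, path) {
  df <- validateClinical(df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
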