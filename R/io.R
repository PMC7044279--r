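#' Read a probe-by-sample expression matrix from TSV
#'
#' The file must be tab-separated with sample identifiers in the first row
#' and probe identifiers in the first column; values are log2-scale
#' intensities. Missing values are written/read as \code{NA} and kept as an
#' explicit missing mask downstream (no imputation).
#'
#' @param path Path to the TSV file.
#' @return A numeric matrix with probe rownames and sample colnames, in file
#'   order.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeExpressionMatrix(matrix(1:6, 2, dimnames = list(c("P1","P2"),
#'                       c("S1","S2","S3"))), f)
#' readExpressionMatrix(f)
#' @export
readExpressionMatrix <- function(path) {
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", na.strings = "NA")
  if (ncol(raw) < 2L) stop("expression file needs a probe-id column and at least one sample")
  probes <- raw[[1L]]
  samples <- colnames(raw)[-1L]
  dup <- probes[duplicated(probes)]
  if (length(dup)) stop(sprintf("duplicate probe id '%s' in %s", dup[1L], path))
  dup <- samples[duplicated(samples)]
  if (length(dup)) stop(sprintf("duplicate sample id '%s' in %s", dup[1L], path))
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric value '%s' at probe '%s', sample '%s'",
                 vals[bad[1L, 1L], bad[1L, 2L]], probes[bad[1L, 1L]],
                 samples[bad[1L, 2L]]))
  dimnames(num) <- list(probes, samples)
  num
}

#' Write an expression matrix as TSV
#'
#' Inverse of \code{\link{readExpressionMatrix}}; values are printed with
#' full precision (17 significant digits) so a write-then-read round trip
#' reproduces them exactly.
#'
#' @param x Numeric matrix with probe rownames and sample colnames.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeExpressionMatrix <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  df <- data.frame(probe_id = rownames(x),
                   format(x, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE)
  colnames(df) <- c("probe_id", colnames(x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical annotation table from TSV
#'
#' Expects one row per sample with a mandatory \code{sample_id} column,
#' survival endpoint columns (\code{os_time}, \code{os_event}, optionally
#' \code{efs_time}, \code{efs_event}) in a single declared time unit
#' (months by convention), and any number of categorical covariate columns.
#' Event flags must be 0/1; times non-negative. Categorical covariates are
#' returned as factors with missing values preserved as an explicit
#' \code{"unknown"} level.
#'
#' @param path Path to the TSV file.
#' @param covariates Optional character vector naming the covariate columns;
#'   defaults to every column other than the ids, endpoints and \code{age}.
#' @return A \code{data.frame} with attribute \code{"covariates"}.
#' @export
readClinicalTable <- function(path, covariates = NULL) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (!"sample_id" %in% colnames(df)) stop("clinical table needs a 'sample_id' column")
  df$sample_id <- as.character(df$sample_id)
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) stop(sprintf("duplicate sample id '%s' in %s", dup[1L], path))
  validateClinical(df)
  reserved <- c("sample_id", "os_time", "os_event", "efs_time", "efs_event", "age")
  if (is.null(covariates)) covariates <- setdiff(colnames(df), reserved)
  missingCov <- setdiff(covariates, colnames(df))
  if (length(missingCov))
    stop(sprintf("declared covariate(s) absent from table: %s",
                 paste(missingCov, collapse = ", ")))
  for (cv in covariates) {
    v <- as.character(df[[cv]])
    v[is.na(v)] <- "unknown"
    df[[cv]] <- factor(v)
  }
  attr(df, "covariates") <- covariates
  df
}

validateClinical <- function(df) {
  for (col in intersect(c("os_time", "efs_time", "age"), colnames(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (any(is.na(v) & !is.na(df[[col]])))
      stop(sprintf("non-numeric value in column '%s'", col))
    if (any(v < 0, na.rm = TRUE))
      stop(sprintf("negative value in column '%s'", col))
    df[[col]] <- v
  }
  for (col in intersect(c("os_event", "efs_event"), colnames(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (!all(v %in% c(0, 1) | is.na(v)))
      stop(sprintf("event flag outside {0,1} in column '%s'", col))
  }
  invisible(df)
}

#' Write a clinical table as TSV
#'
#' @param df Clinical \code{data.frame} as returned by
#'   \code{\link{readClinicalTable}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeClinicalTable <- function(df, path) {
  out <- df
  for (j in seq_along(out)) if (is.factor(out[[j]])) out[[j]] <- as.character(out[[j]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description (discarded), then tab-separated
#' member identifiers. Set names must be unique; each set must be non-empty
#' and free of duplicate members.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors.
#' @export
readGMT <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file")
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    nm <- parts[1L]
    members <- parts[-c(1L, 2L)]
    members <- members[nzchar(members)]
    if (!length(members)) stop(sprintf("gene set '%s' has no members", nm))
    if (anyDuplicated(members))
      stop(sprintf("gene set '%s' contains duplicate member '%s'", nm,
                   members[duplicated(members)][1L]))
    if (nm %in% names(sets)) stop(sprintf("duplicate gene-set name '%s'", nm))
    sets[[nm]] <- members
  }
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field written for every set.
#' @return \code{path}, invisibly.
#' @export
writeGMT <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a ScreenCohort from an expression matrix and clinical table
#'
#' Joins by exact sample-id string match. Samples present in only one of the
#' two inputs are dropped with a message reporting the unmatched ids; the
#' retained sample order follows the expression matrix.
#'
#' @param exprs Numeric probe-by-sample matrix (log2 scale).
#' @param clinical Clinical \code{data.frame} with a \code{sample_id} column
#'   (see \code{\link{readClinicalTable}}).
#' @param covariates Character vector of covariate column names; defaults to
#'   the table's \code{"covariates"} attribute.
#' @return A \linkS4class{ScreenCohort}.
#' @examples
#' sp <- SyntheticCohortSpec(nPatients = 30L, nProbes = 20L, seed = 1L)
#' cohort <- generateCohort(sp)
#' cohort
#' @export
ScreenCohort <- function(exprs, clinical, covariates = NULL) {
  stopifnot(is.matrix(exprs))
  covariates <- covariates %||% attr(clinical, "covariates") %||% character()
  shared <- intersect(colnames(exprs), clinical$sample_id)
  unmatched <- c(setdiff(colnames(exprs), shared),
                 setdiff(clinical$sample_id, shared))
  if (!length(shared)) stop("no sample ids shared between matrix and clinical table")
  if (length(unmatched))
    message(sprintf("dropping %d unmatched sample id(s): %s",
                    length(unmatched), paste(unmatched, collapse = ", ")))
  keep <- colnames(exprs)[colnames(exprs) %in% shared]
  cd <- clinical[match(keep, clinical$sample_id), , drop = FALSE]
  rownames(cd) <- keep
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = exprs[, keep, drop = FALSE]),
    colData = S4Vectors::DataFrame(cd, check.names = FALSE))
  S4Vectors::metadata(se)$covariates <- covariates
  S4Vectors::metadata(se)$unmatched <- unmatched
  methods::new("ScreenCohort", se)
}

#' @describeIn ScreenCohort Expression assay accessor.
#' @param x A ScreenCohort.
#' @export
exprsMatrix <- function(x) SummarizedExperiment::assay(x, "exprs")

#' @describeIn ScreenCohort Clinical annotation as a base data.frame with a
#'   \code{sample_id} column and the covariate attribute restored.
#' @export
clinicalTable <- function(x) {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  cd$sample_id <- colnames(x)
  attr(cd, "covariates") <- S4Vectors::metadata(x)$covariates
  cd
}

#' @describeIn ScreenCohort Names of the balancing covariate columns.
#' @export
covariateNames <- function(x) S4Vectors::metadata(x)$covariates
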