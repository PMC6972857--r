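#' Expression matrix container
#'
#' Wraps a numeric feature-by-sample matrix of log2-scale expression values
#' (log2 of RSEM-normalised counts) together with the feature kind.  Row names
#' are feature identifiers, column names are sample identifiers; both must be
#' unique.  Missing values (\code{NA}) are permitted, all non-missing entries
#' must be finite.
#'
#' @param values Numeric matrix with unique row names (features) and column
#'   names (samples); entries on log2 scale, \code{NA} allowed.
#' @param feature_kind Either \code{"mRNA"} or \code{"miRNA"}.
#' @return An object of class \code{expression_matrix}: a list with elements
#'   \code{values} and \code{feature_kind}.
#' @examples
#' m <- matrix(rnorm(6, 6, 1.5), 3, 2,
#'             dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' expression_matrix(m, "mRNA")
#' @export
expression_matrix <- function(values, feature_kind = c("mRNA", "miRNA")) {
  feature_kind <- match.arg(feature_kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid))
    stop("`values` must carry feature row names and sample column names",
         call. = FALSE)
  if (anyDuplicated(fid))
    stop("duplicate feature ids: ",
         paste(unique(fid[duplicated(fid)]), collapse = ", "), call. = FALSE)
  if (anyDuplicated(sid))
    stop("duplicate sample ids: ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "), call. = FALSE)
  if (any(is.infinite(values)))
    stop("expression values must be finite or missing", call. = FALSE)
  structure(list(values = values, feature_kind = feature_kind),
            class = "expression_matrix")
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d %s features x %d samples (%d missing values)\n",
              nrow(x$values), x$feature_kind, ncol(x$values),
              sum(is.na(x$values))))
  invisible(x)
}

#' Feature and sample identifiers of an expression matrix
#' @param x An \code{expression_matrix}.
#' @return Character vector of identifiers.
#' @export
feature_ids <- function(x) rownames(x$values)

#' @rdname feature_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Read an expression matrix from TSV
#'
#' Expects a tab-separated file with one header row of sample identifiers and
#' feature identifiers in the first column.  Empty cells and the literal
#' \code{NA} denote missing values.  Any other non-numeric cell is a parse
#' error reported with its feature and sample identifier; duplicated feature
#' or sample ids are validation errors.
#'
#' @param path Path to the TSV file.
#' @param feature_kind \code{"mRNA"} or \code{"miRNA"}.
#' @return An \code{\link{expression_matrix}}.
#' @seealso [write_expression_matrix()]
#' @export
read_expression_matrix <- function(path, feature_kind = c("mRNA", "miRNA")) {
  feature_kind <- match.arg(feature_kind)
  raw <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                    check.names = FALSE, colClasses = "character",
                    na.strings = c("", "NA"), stringsAsFactors = FALSE)
  if (ncol(raw) < 2L)
    stop(path, ": expected feature-id column plus at least one sample column",
         call. = FALSE)
  fid <- raw[[1L]]
  sid <- colnames(raw)[-1L]
  vals <- matrix(NA_real_, nrow(raw), length(sid),
                 dimnames = list(fid, sid))
  for (j in seq_along(sid)) {
    cell <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num) & !is.na(cell))
    if (length(bad))
      stop(sprintf("%s: non-numeric cell '%s' at feature '%s', sample '%s' (line %d)",
                   path, cell[bad[1L]], fid[bad[1L]], sid[j], bad[1L] + 1L),
           call. = FALSE)
    vals[, j] <- num
  }
  tryCatch(expression_matrix(vals, feature_kind),
           error = function(e) stop(path, ": ", conditionMessage(e),
                                    call. = FALSE))
}

#' Write an expression matrix to TSV
#'
#' Inverse of \code{\link{read_expression_matrix}}; missing values are written
#' as empty cells.
#'
#' @param x An \code{\link{expression_matrix}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  df <- data.frame(feature_id = feature_ids(x), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}
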