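#' Read a two-group sample sheet from TSV
#'
#' Two-column tab-separated table assigning each sample to one of exactly two
#' groups (e.g. the two tumour subtypes of a cohort).  Columns are taken by
#' name when \code{sample_id}/\code{group} are present, otherwise by position.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns \code{sample_id}, \code{group}.
#' @export
read_sample_sheet <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop(path, ": sample sheet needs two columns (sample_id, group)",
         call. = FALSE)
  if (all(c("sample_id", "group") %in% colnames(df)))
    df <- df[, c("sample_id", "group")]
  else
    df <- setNames(df[, 1:2], c("sample_id", "group"))
  validate_sample_sheet(df, context = path)
}

#' Validate a sample sheet
#'
#' Checks uniqueness of sample ids and that exactly two group labels occur.
#'
#' @param df Data.frame with columns \code{sample_id}, \code{group}.
#' @param context Label used in error messages (e.g. a file name).
#' @return The validated data.frame, invisibly classed as-is.
#' @export
validate_sample_sheet <- function(df, context = "sample sheet") {
  if (anyDuplicated(df$sample_id))
    stop(context, ": duplicated sample id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "),
         call. = FALSE)
  g <- unique(df$group)
  if (length(g) != 2L)
    stop(context, ": expected exactly 2 groups, found ", length(g),
         " (", paste(g, collapse = ", "), ")", call. = FALSE)
  rownames(df) <- NULL
  df
}

#' Write a sample sheet to TSV
#' @param sheet Data.frame with columns \code{sample_id}, \code{group}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_sample_sheet <- function(sheet, path) {
  write.table(sheet[, c("sample_id", "group")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

pair_list_columns <- c("regulator_id", "regulator_class", "target_id",
                       "target_class", "source_tag")

#' Validate a candidate regulator-target pair list
#'
#' Enforces the class model: TF regulators may target \code{gene}, \code{TF}
#' or \code{miRNA}; miRNA regulators may target \code{gene} or \code{TF}
#' (miRNA-to-miRNA regulation has no edge class in this model and is
#' rejected).  Duplicate (regulator, target, source_tag) records are collapsed
#' with a warning.
#'
#' @param df Data.frame with columns \code{regulator_id},
#'   \code{regulator_class}, \code{target_id}, \code{target_class},
#'   \code{source_tag}.
#' @param context Label used in error messages.
#' @return The validated, de-duplicated data.frame.
#' @export
validate_pair_list <- function(df, context = "pair list") {
  miss <- setdiff(pair_list_columns, colnames(df))
  if (length(miss))
    stop(context, ": missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- df[, pair_list_columns]
  bad_rc <- !df$regulator_class %in% c("TF", "miRNA")
  if (any(bad_rc))
    stop(context, ": invalid regulator_class '",
         df$regulator_class[which(bad_rc)[1L]], "' at record ",
         which(bad_rc)[1L], " (rule: regulator_class in {TF, miRNA})",
         call. = FALSE)
  bad_tc <- !df$target_class %in% c("gene", "TF", "miRNA")
  if (any(bad_tc))
    stop(context, ": invalid target_class '",
         df$target_class[which(bad_tc)[1L]], "' at record ",
         which(bad_tc)[1L], " (rule: target_class in {gene, TF, miRNA})",
         call. = FALSE)
  mm <- df$regulator_class == "miRNA" & df$target_class == "miRNA"
  if (any(mm))
    stop(context, ": miRNA regulator with miRNA target at record ",
         which(mm)[1L],
         " (rule: no miRNA->miRNA edge class in the regulation model)",
         call. = FALSE)
  key <- paste(df$regulator_id, df$target_id, df$source_tag, sep = "\r")
  if (anyDuplicated(key)) {
    warning(context, ": collapsed ", sum(duplicated(key)),
            " duplicate (regulator, target, source) record(s)",
            call. = FALSE)
    df <- df[!duplicated(key), , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Read a candidate pair list from TSV
#'
#' Tab-separated table with columns \code{regulator_id},
#' \code{regulator_class}, \code{target_id}, \code{target_class},
#' \code{source_tag}; validated with \code{\link{validate_pair_list}}.
#'
#' @param path Path to the TSV file.
#' @return The validated pair-list data.frame.
#' @export
read_pair_list <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   colClasses = "character", stringsAsFactors = FALSE)
  validate_pair_list(df, context = path)
}

#' Write a candidate pair list to TSV
#' @param pairs Pair-list data.frame.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_pair_list <- function(pairs, path) {
  write.table(pairs[, pair_list_columns], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a TF roster file
#'
#' One gene symbol per line; used to flag which regulator/target identifiers
#' code for transcription factors.
#'
#' @param path Path to the roster file.
#' @return Character vector of unique TF symbols.
#' @export
read_tf_roster <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  unique(x[nzchar(x)])
}

#' Export a regulatory network
#'
#' Writes a \code{\link{build_network}} result in one of three formats:
#' \describe{
#'   \item{\code{sif}}{Cytoscape simple-interaction format, one edge per line
#'     with interaction label \code{activates} or \code{represses}.}
#'   \item{\code{graphml}}{GraphML with node attribute \code{node_class}
#'     (TF/miRNA/gene) and edge attributes \code{sign}, \code{r}, \code{p}.}
#'   \item{\code{tsv}}{Edge table mirroring the GraphML attributes.}
#' }
#'
#' @param network A \code{regulatory_network}.
#' @param path Output path.
#' @param format One of \code{"sif"}, \code{"graphml"}, \code{"tsv"}.
#' @return Invisibly, \code{path}.
#' @export
write_network <- function(network, path, format = c("sif", "graphml", "tsv")) {
  stopifnot(inherits(network, "regulatory_network"))
  format <- match.arg(format)
  e <- network$edges
  if (format == "sif") {
    lines <- if (nrow(e))
      sprintf("%s\t%s\t%s", e$from,
              ifelse(e$sign > 0, "activates", "represses"), e$to)
    else character(0)
    writeLines(lines, path)
  } else if (format == "tsv") {
    write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    igraph::write_graph(network$graph, path, format = "graphml")
  }
  invisible(path)
}

#' Write an FFL table to TSV
#'
#' Columns: the three member identifiers, the category, and r/p for each of
#' the three constituent edges (for MRF the \code{tf_mirna_*} columns hold the
#' miRNA-to-TF edge).
#'
#' @param ffls FFL data.frame from \code{\link{enumerate_ffls}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_ffl_table <- function(ffls, path) {
  write.table(ffls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an FFL table written by [write_ffl_table()]
#' @param path Path to the TSV file.
#' @return FFL data.frame.
#' @export
read_ffl_table <- function(path) {
  read.delim(path, header = TRUE, sep = "\t", quote = "",
             stringsAsFactors = FALSE)
}

#' Write a classification metrics report as JSON
#'
#' @param report An \code{ffl_metrics} object from \code{\link{evaluate_ffl}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_metrics_json <- function(report, path) {
  stopifnot(inherits(report, "ffl_metrics"))
  out <- report[c("sensitivity", "specificity", "precision", "accuracy",
                  "auc", "n_folds", "n_repeats", "seed", "positive_class",
                  "n_samples")]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
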