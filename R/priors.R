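#' Consensus integration of miRNA-target pair lists
#'
#' A (miRNA, target) pair is retained iff it occurs in at least
#' \code{min_support} distinct source databases; the output records carry the
#' merged, comma-separated source tags (sorted, so the result is independent
#' of input order).  TF-target priors come from a single promoter-scan source
#' and bypass this rule.
#'
#' @param lists A list of pair-list data.frames, each carrying one distinct
#'   \code{source_tag} (e.g. one per target-prediction database).
#' @param min_support Minimum number of distinct sources (default 2).
#' @return A pair-list data.frame with merged \code{source_tag}s.
#' @export
consensus_mirna_targets <- function(lists, min_support = 2L) {
  stopifnot(is.list(lists), length(lists) >= 1L, min_support >= 1L)
  lists <- lapply(seq_along(lists), function(i)
    validate_pair_list(lists[[i]], context = paste0("input list ", i)))
  tags <- vapply(lists, function(df) unique(df$source_tag)[1L], "")
  n_tags <- vapply(lists, function(df) length(unique(df$source_tag)), 0L)
  if (any(n_tags != 1L))
    stop("each input list must carry exactly one source_tag", call. = FALSE)
  if (anyDuplicated(tags))
    stop("duplicate source_tag across input lists: ",
         paste(unique(tags[duplicated(tags)]), collapse = ", "),
         call. = FALSE)
  all <- do.call(rbind, lists)
  if (any(all$regulator_class != "miRNA"))
    stop("consensus integration applies to miRNA-regulator pairs only",
         call. = FALSE)
  key <- paste(all$regulator_id, all$target_id, sep = "\r")
  support <- tapply(all$source_tag, key, function(s) length(unique(s)))
  keep_keys <- names(support)[support >= min_support]
  first <- all[!duplicated(key) & key %in% keep_keys, , drop = FALSE]
  merged <- tapply(all$source_tag, key, function(s)
    paste(sort(unique(s)), collapse = ","))
  first$source_tag <- unname(merged[paste(first$regulator_id, first$target_id,
                                          sep = "\r")])
  first <- first[order(first$regulator_id, first$target_id), , drop = FALSE]
  rownames(first) <- NULL
  first
}

#' Flag miRNA targets that code for transcription factors
#'
#' miRNA-to-TF pairs are the subset of consensus miRNA-target pairs whose
#' target appears in a user-supplied TF roster; this sets their
#' \code{target_class} to \code{"TF"}.
#'
#' @param pairs A pair-list data.frame.
#' @param tf_roster Character vector of TF gene symbols (see
#'   \code{\link{read_tf_roster}}).
#' @return The pair list with updated \code{target_class}.
#' @export
apply_tf_roster <- function(pairs, tf_roster) {
  hit <- pairs$regulator_class == "miRNA" & pairs$target_id %in% tf_roster
  pairs$target_class[hit] <- "TF"
  pairs
}

#' Restrict candidate pairs to differentially expressed features
#'
#' A pair is retained iff both its regulator and its target are in the
#' differentially expressed set.
#'
#' @param pairs A pair-list data.frame.
#' @param de Character vector of DE feature ids, or a data.frame with a
#'   \code{feature_id} column.
#' @return The restricted pair list.
#' @export
restrict_to_de <- function(pairs, de) {
  if (is.data.frame(de)) de <- de$feature_id
  out <- pairs[pairs$regulator_id %in% de & pairs$target_id %in% de, ,
               drop = FALSE]
  rownames(out) <- NULL
  out
}
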