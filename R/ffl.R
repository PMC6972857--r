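ffl_columns <- c("tf_id", "mirna_id", "gene_id", "category",
                 "tf_gene_r", "tf_gene_p", "tf_mirna_r", "tf_mirna_p",
                 "mirna_gene_r", "mirna_gene_p")

empty_ffl_table <- function() {
  out <- data.frame(tf_id = character(0), mirna_id = character(0),
                    gene_id = character(0), category = character(0),
                    tf_gene_r = numeric(0), tf_gene_p = numeric(0),
                    tf_mirna_r = numeric(0), tf_mirna_p = numeric(0),
                    mirna_gene_r = numeric(0), mirna_gene_p = numeric(0),
                    stringsAsFactors = FALSE)
  out
}

#' Enumerate coherent TF-miRNA-gene feed-forward loops
#'
#' Emits every (TF, miRNA, gene) triple whose three required directed signed
#' edges all exist in the called regulation pairs, once per satisfied
#' category:
#' \describe{
#'   \item{TRF}{TF activates the miRNA, TF represses the gene, miRNA
#'     represses the gene (the TF represses the gene both directly and via
#'     the miRNA it activates).}
#'   \item{TAF}{TF represses the miRNA, TF activates the gene, miRNA
#'     represses the gene.}
#'   \item{MRF}{miRNA represses the TF, TF activates the gene, miRNA
#'     represses the gene.}
#' }
#' TAF and MRF share the sign pattern but differ in the direction of the
#' TF-miRNA link, so one triple can be emitted under both categories.  The
#' \code{tf_mirna_r}/\code{tf_mirna_p} columns hold the TF-to-miRNA edge for
#' TRF/TAF and the miRNA-to-TF edge for MRF.  Triples with \code{tf_id ==
#' gene_id} are excluded; rows are sorted by category, TF, miRNA, gene, so
#' the output is invariant to input edge order.
#'
#' @param regulations Regulation pairs from \code{\link{call_regulations}}.
#' @return FFL data.frame (one row per triple-category).
#' @export
enumerate_ffls <- function(regulations) {
  reg <- regulations
  pick <- function(rc, tc, type)
    reg[reg$regulator_class == rc & reg$target_class %in% tc &
          reg$regulation_type == type,
        c("regulator_id", "target_id", "r", "p"), drop = FALSE]
  tm_act <- pick("TF", "miRNA", "activation")
  tm_rep <- pick("TF", "miRNA", "repression")
  tg_act <- pick("TF", "gene", "activation")
  tg_rep <- pick("TF", "gene", "repression")
  mg_rep <- pick("miRNA", "gene", "repression")
  mt_rep <- pick("miRNA", "TF", "repression")

  # link: TF<->miRNA edge table keyed by (tf, mirna); direct: TF->gene edges
  assemble <- function(link, tf_col, mir_col, direct, mg, category) {
    if (!nrow(link) || !nrow(direct) || !nrow(mg)) return(empty_ffl_table())
    lk <- data.frame(tf = link[[tf_col]], mirna = link[[mir_col]],
                     link_r = link$r, link_p = link$p,
                     stringsAsFactors = FALSE)
    dr <- data.frame(tf = direct$regulator_id, gene = direct$target_id,
                     tf_gene_r = direct$r, tf_gene_p = direct$p,
                     stringsAsFactors = FALSE)
    a <- merge(lk, dr, by = "tf")
    if (!nrow(a)) return(empty_ffl_table())
    mg_key <- paste(mg$regulator_id, mg$target_id, sep = "\r")
    idx <- match(paste(a$mirna, a$gene, sep = "\r"), mg_key)
    keep <- !is.na(idx) & a$tf != a$gene
    a <- a[keep, , drop = FALSE]; idx <- idx[keep]
    if (!nrow(a)) return(empty_ffl_table())
    data.frame(tf_id = a$tf, mirna_id = a$mirna, gene_id = a$gene,
               category = category,
               tf_gene_r = a$tf_gene_r, tf_gene_p = a$tf_gene_p,
               tf_mirna_r = a$link_r, tf_mirna_p = a$link_p,
               mirna_gene_r = mg$r[idx], mirna_gene_p = mg$p[idx],
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    assemble(tm_act, "regulator_id", "target_id", tg_rep, mg_rep, "TRF"),
    assemble(tm_rep, "regulator_id", "target_id", tg_act, mg_rep, "TAF"),
    assemble(mt_rep, "target_id", "regulator_id", tg_act, mg_rep, "MRF"))
  out <- out[order(match(out$category, c("TRF", "TAF", "MRF")),
                   out$tf_id, out$mirna_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-category FFL count table
#'
#' For each category: the number of FFLs, the distinct TFs, miRNAs and genes
#' involved, and the distinct links of each edge type (TF-gene, TF-miRNA,
#' miRNA-gene, miRNA-TF).
#'
#' @param ffls FFL data.frame from \code{\link{enumerate_ffls}}.
#' @return Data.frame with one row per category present plus the tallies.
#' @export
ffl_count_table <- function(ffls) {
  cats <- c("TRF", "TAF", "MRF")
  do.call(rbind, lapply(cats, function(cc) {
    sub <- ffls[ffls$category == cc, , drop = FALSE]
    link_is_mt <- cc == "MRF"
    data.frame(
      category = cc,
      n_ffls = nrow(sub),
      n_tfs = length(unique(sub$tf_id)),
      n_mirnas = length(unique(sub$mirna_id)),
      n_genes = length(unique(sub$gene_id)),
      links_tf_gene = length(unique(paste(sub$tf_id, sub$gene_id))),
      links_tf_mirna = if (link_is_mt) NA_integer_
                       else length(unique(paste(sub$tf_id, sub$mirna_id))),
      links_mirna_gene = length(unique(paste(sub$mirna_id, sub$gene_id))),
      links_mirna_tf = if (link_is_mt)
                         length(unique(paste(sub$mirna_id, sub$tf_id)))
                       else NA_integer_,
      stringsAsFactors = FALSE)
  }))
}

#' Totals and percentages over per-category FFL counts
#'
#' @param counts Named numeric vector or list with elements \code{TRF},
#'   \code{TAF}, \code{MRF}, or an \code{\link{ffl_count_table}} result.
#' @return List with \code{total} and per-category percentages
#'   (\code{trf_pct}, \code{taf_pct}, \code{mrf_pct}).
#' @export
ffl_tally <- function(counts) {
  if (is.data.frame(counts))
    counts <- setNames(counts$n_ffls, counts$category)
  counts <- unlist(counts)[c("TRF", "TAF", "MRF")]
  if (any(is.na(counts))) stop("need TRF, TAF and MRF counts", call. = FALSE)
  total <- sum(counts)
  pct <- if (total > 0) 100 * counts / total else rep(NA_real_, 3)
  list(total = unname(total), trf_pct = unname(pct[["TRF"]]),
       taf_pct = unname(pct[["TAF"]]), mrf_pct = unname(pct[["MRF"]]))
}

ffl_score <- function(ffls)
  abs(ffls$tf_gene_r) + abs(ffls$tf_mirna_r) + abs(ffls$mirna_gene_r)

#' Top-k FFLs per category by edge strength
#'
#' FFLs are ranked within each category by the sum of the absolute
#' correlations of their three edges (descending); ties are broken
#' lexicographically on (TF, miRNA, gene).  Categories with fewer than
#' \code{k} FFLs return all of them with a warning.
#'
#' @param ffls FFL data.frame.
#' @param k Number of FFLs to keep per category (default 5).
#' @return FFL data.frame with an added \code{score} column.
#' @export
rank_ffls <- function(ffls, k = 5L) {
  if (!nrow(ffls)) return(cbind(ffls, score = numeric(0)))
  ffls$score <- ffl_score(ffls)
  out <- lapply(intersect(c("TRF", "TAF", "MRF"), unique(ffls$category)),
                function(cc) {
    sub <- ffls[ffls$category == cc, , drop = FALSE]
    sub <- sub[order(-sub$score, sub$tf_id, sub$mirna_id, sub$gene_id), ,
               drop = FALSE]
    if (nrow(sub) < k)
      warning("category ", cc, " has only ", nrow(sub), " FFL(s) (< k = ",
              k, ")", call. = FALSE)
    utils::head(sub, k)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Compare the FFL sets of two subtypes
#'
#' An FFL is shared iff the same (TF, miRNA, gene) triple occurs with the same
#' category in both sets.  Also reports node overlaps by class.
#'
#' @param a,b FFL data.frames over the same identifier universe.
#' @return List with \code{shared} (FFL data.frame), \code{shared_by_category}
#'   (named counts), \code{shared_nodes}, \code{a_only_nodes},
#'   \code{b_only_nodes} (data.frames of id, node_class).
#' @export
compare_subtypes <- function(a, b) {
  key <- function(df) paste(df$tf_id, df$mirna_id, df$gene_id, df$category,
                            sep = "\r")
  shared <- a[key(a) %in% key(b), , drop = FALSE]
  rownames(shared) <- NULL
  cats <- c("TRF", "TAF", "MRF")
  by_cat <- setNames(vapply(cats, function(cc)
    sum(shared$category == cc), 0L), cats)
  nodes <- function(df) {
    out <- rbind(data.frame(id = df$tf_id, node_class = "TF"),
                 data.frame(id = df$mirna_id, node_class = "miRNA"),
                 data.frame(id = df$gene_id, node_class = "gene"))
    out[!duplicated(out$id), , drop = FALSE]
  }
  na <- nodes(a); nb <- nodes(b)
  list(shared = shared, shared_by_category = by_cat,
       shared_nodes = na[na$id %in% nb$id, , drop = FALSE],
       a_only_nodes = na[!na$id %in% nb$id, , drop = FALSE],
       b_only_nodes = nb[!nb$id %in% na$id, , drop = FALSE])
}

#' Upper-tail hypergeometric test
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): k successes drawn in a sample
#' of n from a population of N containing K successes.  Computed in log space
#' for numerical stability of extreme tails.
#'
#' @param k Observed successes in the sample.
#' @param K Successes in the population.
#' @param n Sample size.
#' @param N Population size.
#' @return List with \code{k}, \code{K}, \code{n}, \code{N}, \code{p} and
#'   \code{log_p} (natural log of the p-value).
#' @export
hypergeometric_upper <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || k > min(K, n) || K > N || n > N)
    stop("inconsistent hypergeometric counts: need 0 <= k <= min(K, n) <= N",
         call. = FALSE)
  log_p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
  list(k = k, K = K, n = n, N = N, p = exp(log_p), log_p = log_p)
}
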