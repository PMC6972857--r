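#' Assemble a regulatory network from FFLs
#'
#' Nodes are the union of FFL members (a node appearing both as TF and as
#' gene across FFLs is labelled TF); directed signed edges are the
#' de-duplicated union of the constituent regulation pairs (TF-to-gene,
#' TF-to-miRNA or miRNA-to-TF depending on category, miRNA-to-gene).  Per
#' node the out-degree, in-degree and local clustering coefficient (computed
#' on the undirected sign-blind projection, self-loops excluded) are
#' reported, along with the mean total degree \eqn{\sum(in+out)/N}.
#'
#' @param ffls FFL data.frame from \code{\link{enumerate_ffls}}; empty input
#'   gives an empty network.
#' @return An object of class \code{regulatory_network}: list with
#'   \code{nodes} (id, node_class, out_degree, in_degree, clustering),
#'   \code{edges} (from, from_class, to, to_class, sign, r, p), \code{graph}
#'   (igraph) and \code{stats}.
#' @export
build_network <- function(ffls) {
  edge_rows <- function(f) {
    mt <- f$category == "MRF"
    rbind(
      data.frame(from = f$tf_id, from_class = "TF", to = f$gene_id,
                 to_class = "gene", r = f$tf_gene_r, p = f$tf_gene_p,
                 stringsAsFactors = FALSE),
      data.frame(from = ifelse(mt, f$mirna_id, f$tf_id),
                 from_class = ifelse(mt, "miRNA", "TF"),
                 to = ifelse(mt, f$tf_id, f$mirna_id),
                 to_class = ifelse(mt, "TF", "miRNA"),
                 r = f$tf_mirna_r, p = f$tf_mirna_p,
                 stringsAsFactors = FALSE),
      data.frame(from = f$mirna_id, from_class = "miRNA", to = f$gene_id,
                 to_class = "gene", r = f$mirna_gene_r, p = f$mirna_gene_p,
                 stringsAsFactors = FALSE))
  }
  if (nrow(ffls)) {
    e <- edge_rows(ffls)
    e <- e[!duplicated(paste(e$from, e$to, sep = "\r")), , drop = FALSE]
    e$sign <- ifelse(e$r > 0, 1L, -1L)
    e <- e[, c("from", "from_class", "to", "to_class", "sign", "r", "p")]
    rownames(e) <- NULL
    nd <- rbind(data.frame(id = c(e$from, e$to),
                           node_class = c(e$from_class, e$to_class),
                           stringsAsFactors = FALSE))
    # class priority TF > miRNA > gene for nodes seen under several roles
    nd$rank <- match(nd$node_class, c("TF", "miRNA", "gene"))
    nd <- nd[order(nd$id, nd$rank), , drop = FALSE]
    nd <- nd[!duplicated(nd$id), c("id", "node_class"), drop = FALSE]
    nd <- nd[order(nd$id), , drop = FALSE]
    rownames(nd) <- NULL
  } else {
    e <- data.frame(from = character(0), from_class = character(0),
                    to = character(0), to_class = character(0),
                    sign = integer(0), r = numeric(0), p = numeric(0),
                    stringsAsFactors = FALSE)
    nd <- data.frame(id = character(0), node_class = character(0),
                     stringsAsFactors = FALSE)
  }
  g <- igraph::graph_from_data_frame(
    e[, c("from", "to", "sign", "r", "p")], directed = TRUE,
    vertices = nd)
  if (nrow(nd)) {
    nd$out_degree <- as.integer(igraph::degree(g, mode = "out"))
    nd$in_degree <- as.integer(igraph::degree(g, mode = "in"))
    und <- igraph::as_undirected(g, mode = "collapse")
    cc <- igraph::transitivity(und, type = "localundirected",
                               isolates = "zero")
    nd$clustering <- ifelse(is.nan(cc), 0, cc)
  } else {
    nd$out_degree <- integer(0); nd$in_degree <- integer(0)
    nd$clustering <- numeric(0)
  }
  stats <- list(
    n_nodes = nrow(nd),
    n_by_class = c(TF = sum(nd$node_class == "TF"),
                   miRNA = sum(nd$node_class == "miRNA"),
                   gene = sum(nd$node_class == "gene")),
    n_edges = nrow(e),
    mean_total_degree = if (nrow(nd))
      sum(nd$out_degree + nd$in_degree) / nrow(nd) else NA_real_)
  structure(list(nodes = nd, edges = e, graph = g, stats = stats),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  s <- x$stats
  cat(sprintf("<regulatory_network> %d nodes (%d TFs, %d miRNAs, %d genes), %d links, mean degree %.1f\n",
              s$n_nodes, s$n_by_class[["TF"]], s$n_by_class[["miRNA"]],
              s$n_by_class[["gene"]], s$n_edges,
              ifelse(is.na(s$mean_total_degree), 0, s$mean_total_degree)))
  invisible(x)
}

#' Degree-based hub detection
#'
#' Hubs are the nodes in the top \code{quantile} fraction of the out-degree
#' ranking, united with the top fraction of the in-degree ranking; all nodes
#' tied with the cutoff value are included.  The basis records whether a node
#' qualified by out-degree, in-degree, or both.
#'
#' @param net A \code{regulatory_network} (non-empty).
#' @param quantile Fraction of top-ranked nodes per degree direction, in
#'   (0, 1); default 0.2.
#' @return Data.frame with columns \code{node}, \code{node_class},
#'   \code{out_degree}, \code{in_degree}, \code{basis}.
#' @export
find_hubs <- function(net, quantile = 0.2) {
  stopifnot(inherits(net, "regulatory_network"))
  if (quantile <= 0 || quantile >= 1)
    stop("quantile must be in (0, 1)", call. = FALSE)
  nd <- net$nodes
  if (!nrow(nd)) stop("cannot find hubs in an empty network", call. = FALSE)
  k <- ceiling(quantile * nrow(nd))
  top_ids <- function(deg) {
    cutoff <- sort(deg, decreasing = TRUE)[k]
    nd$id[deg >= cutoff]
  }
  out_ids <- top_ids(nd$out_degree)
  in_ids <- top_ids(nd$in_degree)
  hubs <- union(out_ids, in_ids)
  if (length(hubs) == nrow(nd) && nrow(nd) > k)
    warning("all nodes tied at the hub cutoff; returning every node",
            call. = FALSE)
  res <- nd[nd$id %in% hubs, c("id", "node_class", "out_degree", "in_degree"),
            drop = FALSE]
  res$basis <- ifelse(res$id %in% out_ids & res$id %in% in_ids, "both",
                      ifelse(res$id %in% out_ids, "out", "in"))
  colnames(res)[1L] <- "node"
  res <- res[order(-pmax(res$out_degree, res$in_degree), res$node), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}
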