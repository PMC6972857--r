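#' Run the full FFL analysis pipeline
#'
#' Filters the expression matrices, calls differential expression between the
#' two groups, restricts the candidate priors to DE features, calls
#' significant signed regulation pairs by Pearson correlation, enumerates the
#' three coherent FFL categories, and assembles the regulatory network with
#' hub detection.
#'
#' @param mrna,mirna \code{\link{expression_matrix}} objects.
#' @param sheet Two-group sample sheet.
#' @param priors Candidate pair-list data.frame.
#' @param filter_cfg A \code{\link{filter_config}}.
#' @param edge_cfg An \code{\link{edge_config}}.  If its
#'   \code{sample_subset} is NULL and \code{group} is given, correlations are
#'   computed within that group's samples.
#' @param group Optional group label naming the subtype analysis; selects the
#'   correlation sample subset and is recorded as the edge
#'   \code{group_context}.  \code{NULL} uses the combined cohort.
#' @param hub_quantile Top-degree fraction for \code{\link{find_hubs}}.
#' @param de_method Passed to \code{\link{differential_expression}}.
#' @return A list with elements \code{de_mrna}, \code{de_mirna} (DE tables),
#'   \code{de_called} (called features), \code{priors_de} (restricted
#'   priors), \code{regulations}, \code{count_table}, \code{ffls},
#'   \code{ffl_counts}, \code{network}, \code{hubs}.
#' @export
run_ffl_pipeline <- function(mrna, mirna, sheet, priors,
                             filter_cfg = filter_config(),
                             edge_cfg = edge_config(),
                             group = NULL, hub_quantile = 0.2,
                             de_method = "moderated") {
  sheet <- validate_sample_sheet(sheet)
  fm <- filter_genes(mrna, filter_cfg)
  fmi <- filter_mirnas(mirna, filter_cfg)
  de_mrna <- differential_expression(fm, sheet, method = de_method)
  de_mirna <- differential_expression(fmi, sheet, method = de_method)
  de_called <- rbind(call_de(de_mrna, filter_cfg),
                     call_de(de_mirna, filter_cfg))
  priors_de <- restrict_to_de(priors, de_called$feature_id)
  if (!is.null(group)) {
    if (!group %in% sheet$group)
      stop("group '", group, "' not present in the sample sheet",
           call. = FALSE)
    if (is.null(edge_cfg$sample_subset))
      edge_cfg$sample_subset <- intersect(
        sheet$sample_id[sheet$group == group],
        intersect(sample_ids(fm), sample_ids(fmi)))
    context <- group
  } else {
    context <- "all"
  }
  regulations <- call_regulations(fm, fmi, priors_de, edge_cfg,
                                  group_context = context)
  ffls <- enumerate_ffls(regulations)
  network <- build_network(ffls)
  hubs <- if (network$stats$n_nodes > 0)
    find_hubs(network, quantile = hub_quantile) else NULL
  list(de_mrna = de_mrna, de_mirna = de_mirna, de_called = de_called,
       priors_de = priors_de, regulations = regulations,
       count_table = regulation_count_table(regulations),
       ffls = ffls, ffl_counts = ffl_count_table(ffls),
       network = network, hubs = hubs)
}
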