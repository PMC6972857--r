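#' Pearson correlation with a two-sided t-based p-value
#'
#' Uses pairwise-complete observations.  The p-value comes from
#' \eqn{t = r \sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} degrees of freedom;
#' \eqn{|r| = 1} gives p = 0.  Fewer than 3 complete pairs is an error; zero
#' variance in either series is flagged (\code{r} and \code{p} are NA) so the
#' caller can skip the pair.
#'
#' @param x,y Numeric vectors of equal length; NAs allowed.
#' @return List with \code{r}, \code{p}, \code{n} (complete pairs) and
#'   \code{flag} (\code{NA} or \code{"zero_variance"}).
#' @export
pearson_test <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3L)
    stop("need at least 3 complete observation pairs (got ", n, ")",
         call. = FALSE)
  xs <- x[ok]; ys <- y[ok]
  if (sd(xs) == 0 || sd(ys) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, flag = "zero_variance"))
  r <- cor(xs, ys)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tt), n - 2)
  }
  list(r = r, p = p, n = n, flag = NA_character_)
}

#' Configuration for correlation-based edge calling
#'
#' @param max_p Raw p-value cutoff (strict), default 0.05.
#' @param min_abs_r Optional magnitude threshold on |r| (strict; applied to
#'   the absolute correlation so repression edges are not discarded);
#'   \code{NULL} disables it.
#' @param sample_subset Optional character vector of sample ids entering the
#'   correlations; \code{NULL} uses all samples common to both matrices
#'   (combined cohort).
#' @param p_adjust \code{"none"} (default; raw p-values are thresholded) or
#'   \code{"BH"} to threshold Benjamini-Hochberg adjusted p-values instead.
#' @return A list of class \code{edge_config}.
#' @export
edge_config <- function(max_p = 0.05, min_abs_r = NULL, sample_subset = NULL,
                        p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  if (max_p <= 0 || max_p > 1) stop("max_p must be in (0, 1]", call. = FALSE)
  if (!is.null(min_abs_r) && (min_abs_r < 0 || min_abs_r >= 1))
    stop("min_abs_r must be in [0, 1)", call. = FALSE)
  structure(list(max_p = max_p, min_abs_r = min_abs_r,
                 sample_subset = sample_subset, p_adjust = p_adjust),
            class = "edge_config")
}

#' Call significant signed regulation pairs from candidate priors
#'
#' For every candidate prior pair the Pearson correlation between regulator
#' and target expression is computed over the configured sample subset.  A
#' pair is kept iff its p-value passes \code{max_p}, its |r| passes
#' \code{min_abs_r} when set, and the class-specific sign rule holds: a TF
#' regulator may correlate either way (activation when r > 0, repression when
#' r < 0) while a miRNA regulator is kept only with r < 0 (repression).
#' Self-pairs are dropped; priors whose endpoints are absent from the
#' matrices, or with zero-variance expression, are skipped and logged in the
#' \code{skipped} attribute.
#'
#' @param mrna mRNA \code{\link{expression_matrix}} (genes and TF-coding
#'   genes).
#' @param mirna miRNA \code{\link{expression_matrix}}.
#' @param priors Candidate pair-list data.frame.
#' @param cfg An \code{\link{edge_config}}.
#' @param group_context Label recording which subtype analysis produced the
#'   pairs (stored in the result).
#' @return Data.frame of regulation pairs with columns \code{regulator_id},
#'   \code{regulator_class}, \code{target_id}, \code{target_class}, \code{r},
#'   \code{p}, \code{regulation_type}, \code{group_context}; attribute
#'   \code{skipped} lists skipped priors with the reason.
#' @export
call_regulations <- function(mrna, mirna, priors, cfg = edge_config(),
                             group_context = "all") {
  stopifnot(inherits(mrna, "expression_matrix"),
            inherits(mirna, "expression_matrix"),
            inherits(cfg, "edge_config"))
  priors <- priors[!duplicated(paste(priors$regulator_id, priors$target_id,
                                     sep = "\r")), , drop = FALSE]
  priors <- priors[priors$regulator_id != priors$target_id, , drop = FALSE]
  samples <- intersect(sample_ids(mrna), sample_ids(mirna))
  if (!is.null(cfg$sample_subset)) {
    missing_s <- setdiff(cfg$sample_subset, samples)
    if (length(missing_s))
      stop("sample_subset contains unknown sample(s): ",
           paste(utils::head(missing_s, 3), collapse = ", "), call. = FALSE)
    samples <- cfg$sample_subset
  }
  series <- function(id, class) {
    mat <- if (class == "miRNA") mirna else mrna
    if (!id %in% feature_ids(mat)) return(NULL)
    mat$values[id, samples]
  }
  n <- nrow(priors)
  r <- p <- rep(NA_real_, n)
  skip_reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    x <- series(priors$regulator_id[i], priors$regulator_class[i])
    y <- series(priors$target_id[i], priors$target_class[i])
    if (is.null(x) || is.null(y)) {
      skip_reason[i] <- "endpoint_absent"
      next
    }
    ct <- pearson_test(x, y)
    if (!is.na(ct$flag)) {
      skip_reason[i] <- ct$flag
      next
    }
    r[i] <- ct$r; p[i] <- ct$p
  }
  skipped <- priors[!is.na(skip_reason), , drop = FALSE]
  if (nrow(skipped)) {
    skipped$reason <- skip_reason[!is.na(skip_reason)]
    message(nrow(skipped), " prior pair(s) skipped (endpoint absent or zero ",
            "variance)")
  }
  computed <- is.na(skip_reason)
  p_eff <- p
  if (cfg$p_adjust == "BH") p_eff[computed] <- p.adjust(p[computed], "BH")
  keep <- computed & p_eff < cfg$max_p
  if (!is.null(cfg$min_abs_r)) keep <- keep & abs(r) > cfg$min_abs_r
  keep <- keep & !(priors$regulator_class == "miRNA" & r >= 0)
  out <- data.frame(
    regulator_id = priors$regulator_id[keep],
    regulator_class = priors$regulator_class[keep],
    target_id = priors$target_id[keep],
    target_class = priors$target_class[keep],
    r = r[keep], p = p_eff[keep],
    regulation_type = ifelse(r[keep] > 0, "activation", "repression"),
    group_context = group_context,
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "skipped") <- skipped
  attr(out, "n_samples") <- length(samples)
  out
}

regulation_classes <- data.frame(
  regulation_class = c("TF-gene", "TF-gene", "TF-miRNA", "TF-miRNA",
                       "miRNA-gene", "miRNA-TF"),
  regulation_type = c("activation", "repression", "activation", "repression",
                      "repression", "repression"),
  stringsAsFactors = FALSE)

# Map a regulation-pair table onto the four regulation classes.  TF targets
# that are themselves TF-coding genes fall in the TF-gene class.
classify_regulations <- function(pairs) {
  ifelse(pairs$regulator_class == "TF",
         ifelse(pairs$target_class == "miRNA", "TF-miRNA", "TF-gene"),
         ifelse(pairs$target_class == "TF", "miRNA-TF", "miRNA-gene"))
}

#' Per-class regulation count table
#'
#' Summarises called regulation pairs in the standard six-row layout: TF-gene
#' activation/repression, TF-miRNA activation/repression, miRNA-gene
#' repression, miRNA-TF repression, with the number of pairs and of distinct
#' miRNAs, TFs and genes involved in each row.
#'
#' @param pairs Regulation pairs from \code{\link{call_regulations}}.
#' @return Data.frame with columns \code{regulation_class},
#'   \code{regulation_type}, \code{n_pairs}, \code{n_mirnas}, \code{n_tfs},
#'   \code{n_genes}.
#' @export
regulation_count_table <- function(pairs) {
  cls <- classify_regulations(pairs)
  out <- regulation_classes
  out$n_pairs <- 0L
  out$n_mirnas <- NA_integer_; out$n_tfs <- NA_integer_
  out$n_genes <- NA_integer_
  for (i in seq_len(nrow(out))) {
    sel <- cls == out$regulation_class[i] &
      pairs$regulation_type == out$regulation_type[i]
    out$n_pairs[i] <- sum(sel)
    sub <- pairs[sel, , drop = FALSE]
    regs <- unique(sub$regulator_id); tgts <- unique(sub$target_id)
    out[i, c("n_mirnas", "n_tfs", "n_genes")] <- switch(
      out$regulation_class[i],
      "TF-gene" = c(NA_integer_, length(regs), length(tgts)),
      "TF-miRNA" = c(length(tgts), length(regs), NA_integer_),
      "miRNA-gene" = c(length(regs), NA_integer_, length(tgts)),
      "miRNA-TF" = c(length(regs), length(tgts), NA_integer_))
  }
  out
}

#' Build a count table from per-class pair counts
#'
#' Convenience constructor for bookkeeping: takes the six per-class counts in
#' the standard layout and returns the same table
#' \code{\link{regulation_count_table}} produces (identifier tallies NA).
#'
#' @param tf_gene_act,tf_gene_rep,tf_mirna_act,tf_mirna_rep Per-class TF-pair
#'   counts.
#' @param mirna_gene,mirna_tf Per-class miRNA-pair counts (repression only).
#' @return Count-table data.frame.
#' @export
regulation_counts <- function(tf_gene_act, tf_gene_rep, tf_mirna_act,
                              tf_mirna_rep, mirna_gene, mirna_tf) {
  out <- regulation_classes
  out$n_pairs <- as.integer(c(tf_gene_act, tf_gene_rep, tf_mirna_act,
                              tf_mirna_rep, mirna_gene, mirna_tf))
  if (any(out$n_pairs < 0L)) stop("counts must be non-negative", call. = FALSE)
  out$n_mirnas <- NA_integer_; out$n_tfs <- NA_integer_
  out$n_genes <- NA_integer_
  out
}

#' Totals and percentages over a regulation count table
#'
#' Computes the grand total, the TF-mediated pair count and its percentage of
#' the total, the activation count among TF-mediated pairs and its percentage,
#' and the miRNA-mediated pair count.
#'
#' @param counts Count table from \code{\link{regulation_count_table}} or
#'   \code{\link{regulation_counts}}.
#' @return List with \code{total}, \code{tf_pairs}, \code{tf_pct},
#'   \code{tf_activation}, \code{tf_activation_pct}, \code{mirna_pairs}.
#' @export
regulation_tally <- function(counts) {
  stopifnot(all(c("regulation_class", "regulation_type", "n_pairs") %in%
                  colnames(counts)))
  tf <- grepl("^TF-", counts$regulation_class)
  total <- sum(counts$n_pairs)
  tf_pairs <- sum(counts$n_pairs[tf])
  tf_act <- sum(counts$n_pairs[tf & counts$regulation_type == "activation"])
  list(total = total,
       tf_pairs = tf_pairs,
       tf_pct = if (total > 0) 100 * tf_pairs / total else NA_real_,
       tf_activation = tf_act,
       tf_activation_pct = if (tf_pairs > 0) 100 * tf_act / tf_pairs
                           else NA_real_,
       mirna_pairs = total - tf_pairs)
}
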