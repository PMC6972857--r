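#' Expression filtering and differential-expression thresholds
#'
#' Defaults encode the analysis rules: drop genes whose log2 level is below 1
#' in more than 50\% of samples; drop miRNAs missing in more than 10\% of
#' samples or not above log2 3.46 in more than 10\% of samples; call a feature
#' differentially expressed at |log2 fold-change| >= 1 (at least 2-fold) with
#' Benjamini-Hochberg adjusted p below 0.05.
#'
#' @param gene_min_log2 Gene low-expression threshold (log2 units).
#' @param gene_max_frac_below Maximum tolerated fraction of samples below
#'   \code{gene_min_log2} ("more than" is strict).
#' @param mirna_max_missing_frac Maximum tolerated missing fraction.
#' @param mirna_min_log2 miRNA expression threshold (log2 units).
#' @param mirna_min_frac_above Required fraction of samples above
#'   \code{mirna_min_log2} (strictly more than; denominator is all samples,
#'   missing cells counted as not-above).
#' @param de_min_abs_log2fc Minimum |log2 fold-change| for a DE call
#'   (inclusive).
#' @param de_max_p_adj Adjusted-p cutoff for a DE call (strict).
#' @return A list of class \code{filter_config}.
#' @export
filter_config <- function(gene_min_log2 = 1, gene_max_frac_below = 0.5,
                          mirna_max_missing_frac = 0.1,
                          mirna_min_log2 = 3.46, mirna_min_frac_above = 0.1,
                          de_min_abs_log2fc = 1, de_max_p_adj = 0.05) {
  cfg <- list(gene_min_log2 = gene_min_log2,
              gene_max_frac_below = gene_max_frac_below,
              mirna_max_missing_frac = mirna_max_missing_frac,
              mirna_min_log2 = mirna_min_log2,
              mirna_min_frac_above = mirna_min_frac_above,
              de_min_abs_log2fc = de_min_abs_log2fc,
              de_max_p_adj = de_max_p_adj)
  fr <- c(cfg$gene_max_frac_below, cfg$mirna_max_missing_frac,
          cfg$mirna_min_frac_above)
  if (any(fr < 0 | fr > 1)) stop("fractions must be in [0, 1]", call. = FALSE)
  if (any(!is.finite(unlist(cfg)))) stop("thresholds must be finite",
                                         call. = FALSE)
  structure(cfg, class = "filter_config")
}

#' Filter lowly expressed genes
#'
#' A gene is retained iff the fraction of samples with a (non-missing) value
#' below \code{gene_min_log2} is at most \code{gene_max_frac_below}; "below in
#' more than half the samples" removes, exactly half retains.
#'
#' @param m An mRNA \code{\link{expression_matrix}}.
#' @param cfg A \code{\link{filter_config}}.
#' @return The filtered \code{expression_matrix}.
#' @export
filter_genes <- function(m, cfg = filter_config()) {
  stopifnot(inherits(m, "expression_matrix"), m$feature_kind == "mRNA")
  if (nrow(m$values) == 0L) {
    warning("empty expression matrix", call. = FALSE)
    return(m)
  }
  frac_below <- rowSums(m$values < cfg$gene_min_log2, na.rm = TRUE) /
    ncol(m$values)
  keep <- frac_below <= cfg$gene_max_frac_below
  expression_matrix(m$values[keep, , drop = FALSE], "mRNA")
}

#' Filter miRNAs by missingness and expression level
#'
#' A miRNA is retained iff its missing fraction is at most
#' \code{mirna_max_missing_frac} and its value exceeds \code{mirna_min_log2}
#' in strictly more than \code{mirna_min_frac_above} of all samples (missing
#' cells count in the denominator, not as above-threshold).
#'
#' @param m A miRNA \code{\link{expression_matrix}}.
#' @param cfg A \code{\link{filter_config}}.
#' @return The filtered \code{expression_matrix}.
#' @export
filter_mirnas <- function(m, cfg = filter_config()) {
  stopifnot(inherits(m, "expression_matrix"), m$feature_kind == "miRNA")
  if (nrow(m$values) == 0L) {
    warning("empty expression matrix", call. = FALSE)
    return(m)
  }
  ns <- ncol(m$values)
  missing_frac <- rowMeans(is.na(m$values))
  frac_above <- rowSums(m$values > cfg$mirna_min_log2, na.rm = TRUE) / ns
  keep <- missing_frac <= cfg$mirna_max_missing_frac &
    frac_above > cfg$mirna_min_frac_above
  expression_matrix(m$values[keep, , drop = FALSE], "miRNA")
}

# Invert the trigamma function by Newton iteration (monotone decreasing on
# (0, Inf)); used to fit the prior degrees of freedom of the variance model.
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (it in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, deriv = 2L)
      y <- y + dif
      if (abs(dif) < 1e-8 * y) break
    }
    y
  }, numeric(1))
}

# Method-of-moments fit of the scaled inverse-chi-square prior on residual
# variances: log s^2 is matched to the log-F moments via digamma/trigamma.
# Returns prior df d0 (possibly Inf) and prior variance s0^2.
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0 & df > 0
  if (sum(ok) < 2L)
    stop("need at least two features with positive residual variance to fit ",
         "the variance prior", call. = FALSE)
  z <- log(s2[ok])
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  emean <- mean(e)
  evar <- var(e) - mean(trigamma(df[ok] / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess spread in log s^2 beyond sampling noise: variances look
    # common, so the prior is the plain mean variance with infinite df
    d0 <- Inf
    s02 <- mean(s2[ok])
  }
  list(d0 = d0, s02 = s02)
}

#' Two-group differential expression with a moderated t-statistic
#'
#' For every feature the log2 fold-change is the difference of group means
#' (group 1 minus group 2) computed on the log2 scale with missing values
#' dropped per group.  The per-feature pooled residual variance s^2 (df
#' \eqn{d = n_1 + n_2 - 2}) is shrunk towards a common prior fitted by method
#' of moments on log variances, giving \eqn{\tilde s^2 = (d_0 s_0^2 + d s^2) /
#' (d_0 + d)}; the moderated t is the fold-change over \eqn{\tilde s
#' \sqrt{1/n_1 + 1/n_2}} with a two-sided p-value on \eqn{d_0 + d} degrees of
#' freedom.  P-values are Benjamini-Hochberg adjusted across all features of
#' the matrix.  Zero-variance features are handled through the shrunken
#' variance (no division by zero while \eqn{d_0 > 0}).
#'
#' @param m An \code{\link{expression_matrix}} (already filtered).
#' @param sheet Sample sheet data.frame (\code{sample_id}, \code{group}); at
#'   least two samples per group.
#' @param method \code{"moderated"} (default) or \code{"welch"} for a plain
#'   Welch two-sample t-test.
#' @param contrast Optional length-2 character vector naming (group 1,
#'   group 2); default is the sorted group labels.
#' @param prior Optional list \code{list(d0 =, s02 =)} fixing the variance
#'   prior instead of fitting it; \code{d0 = 0} reduces the moderated t to the
#'   ordinary pooled two-sample t.
#' @return A data.frame with columns \code{feature_id}, \code{log2fc},
#'   \code{t}, \code{p_raw}, \code{p_adj}, \code{direction}; attributes
#'   \code{groups} and (for the moderated method) \code{prior}.
#' @export
differential_expression <- function(m, sheet,
                                    method = c("moderated", "welch"),
                                    contrast = NULL, prior = NULL) {
  stopifnot(inherits(m, "expression_matrix"))
  method <- match.arg(method)
  sheet <- sheet[sheet$sample_id %in% sample_ids(m), , drop = FALSE]
  groups <- sort(unique(sheet$group))
  if (length(groups) != 2L)
    stop("sample sheet must define exactly two groups among the matrix ",
         "samples", call. = FALSE)
  if (!is.null(contrast)) {
    if (!setequal(contrast, groups))
      stop("`contrast` must name the two group labels", call. = FALSE)
    groups <- contrast
  }
  s1 <- sheet$sample_id[sheet$group == groups[1L]]
  s2 <- sheet$sample_id[sheet$group == groups[2L]]
  if (length(s1) < 2L || length(s2) < 2L)
    stop("each group needs at least 2 samples (found ", length(s1), " and ",
         length(s2), ")", call. = FALSE)
  x1 <- m$values[, s1, drop = FALSE]
  x2 <- m$values[, s2, drop = FALSE]
  n1 <- rowSums(!is.na(x1)); n2 <- rowSums(!is.na(x2))
  m1 <- rowMeans(x1, na.rm = TRUE); m2 <- rowMeans(x2, na.rm = TRUE)
  log2fc <- m1 - m2
  rss <- rowSums((x1 - m1)^2, na.rm = TRUE) + rowSums((x2 - m2)^2, na.rm = TRUE)
  df <- n1 + n2 - 2
  usable <- n1 >= 2L & n2 >= 2L
  if (any(!usable))
    warning(sum(!usable), " feature(s) with fewer than 2 non-missing values ",
            "in a group: statistics set to NA", call. = FALSE)
  s2p <- ifelse(usable, rss / pmax(df, 1L), NA_real_)

  if (method == "moderated") {
    if (is.null(prior)) prior <- fit_variance_prior(s2p[usable], df[usable])
    d0 <- prior$d0; s02 <- prior$s02
    if (is.finite(d0)) {
      s2t <- (d0 * s02 + df * s2p) / (d0 + df)
      df_tot <- d0 + df
    } else {
      s2t <- rep(s02, length(s2p))
      df_tot <- rep(Inf, length(s2p))
    }
    tt <- log2fc / sqrt(s2t * (1 / n1 + 1 / n2))
    p <- 2 * pt(-abs(tt), df_tot)
  } else {
    v1 <- ifelse(usable, rowSums((x1 - m1)^2, na.rm = TRUE) / (n1 - 1), NA_real_)
    v2 <- ifelse(usable, rowSums((x2 - m2)^2, na.rm = TRUE) / (n2 - 1), NA_real_)
    se2 <- v1 / n1 + v2 / n2
    tt <- log2fc / sqrt(se2)
    df_w <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * pt(-abs(tt), df_w)
    prior <- NULL
  }
  tt[!usable] <- NA_real_; p[!usable] <- NA_real_
  out <- data.frame(feature_id = feature_ids(m), log2fc = log2fc, t = tt,
                    p_raw = p, p_adj = p.adjust(p, method = "BH"),
                    direction = ifelse(log2fc > 0, "up", "down"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "groups") <- groups
  attr(out, "prior") <- prior
  out
}

#' Call differentially expressed features
#'
#' A feature is called iff \code{|log2fc| >= de_min_abs_log2fc} (at least
#' 2-fold at the default 1) and \code{p_adj < de_max_p_adj}.
#'
#' @param records DE table from \code{\link{differential_expression}}.
#' @param cfg A \code{\link{filter_config}}.
#' @return Data.frame with columns \code{feature_id}, \code{direction}.
#' @export
call_de <- function(records, cfg = filter_config()) {
  if (!nrow(records))
    return(data.frame(feature_id = character(0), direction = character(0),
                      stringsAsFactors = FALSE))
  keep <- !is.na(records$p_adj) &
    abs(records$log2fc) >= cfg$de_min_abs_log2fc &
    records$p_adj < cfg$de_max_p_adj
  out <- records[keep, c("feature_id", "direction")]
  rownames(out) <- NULL
  out
}

#' Fold-change direction concordance between two DE tables
#'
#' For every feature shared by the two tables the call is concordant iff the
#' log2 fold-changes have the same sign; used to check that hub regulators
#' show the same regulatory pattern in an independent dataset.
#'
#' @param a,b DE tables (data.frames with \code{feature_id}, \code{log2fc}).
#' @return A list with \code{table} (feature_id, log2fc_a, log2fc_b,
#'   concordant), \code{n_shared}, \code{n_concordant} and \code{fraction}.
#' @export
direction_concordance <- function(a, b) {
  tab <- merge(a[, c("feature_id", "log2fc")], b[, c("feature_id", "log2fc")],
               by = "feature_id", suffixes = c("_a", "_b"))
  if (!nrow(tab)) {
    warning("no shared features between the two DE tables", call. = FALSE)
    tab$concordant <- logical(0)
    return(list(table = tab, n_shared = 0L, n_concordant = 0L,
                fraction = NA_real_))
  }
  tab$concordant <- sign(tab$log2fc_a) == sign(tab$log2fc_b)
  list(table = tab, n_shared = nrow(tab),
       n_concordant = sum(tab$concordant),
       fraction = mean(tab$concordant))
}
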