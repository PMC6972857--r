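#' Configuration for the synthetic two-group dataset
#'
#' Defaults mirror the study conditions the pipeline was designed for: a
#' 48-vs-55 two-group cohort, a 2 log2-unit planted group difference (the
#' 2-fold differential-expression rule), and a coupling strength/noise pair
#' giving planted within-group Pearson correlations of roughly 0.83-0.92.
#'
#' @param n_group1,n_group2 Sample counts for the two groups.
#' @param n_genes,n_tfs,n_mirnas Background feature counts (TF-coding genes
#'   live in the mRNA matrix alongside the other genes).
#' @param n_planted_per_category Number of planted FFLs for each of the three
#'   categories (TRF, TAF, MRF).
#' @param effect_beta Linear coupling strength of planted pairs (log2 units
#'   per log2 unit of regulator expression).
#' @param noise_sd Residual standard deviation of planted targets (log2
#'   units).
#' @param de_log2fc Planted group-mean difference for differentially
#'   expressed features (log2 units).
#' @param mirna_missing_rate Fraction of miRNA-matrix entries masked missing;
#'   keep below 0.1 so planted miRNAs survive the missingness filter.
#' @param n_decoy_pairs Candidate prior pairs with no planted coupling.
#' @param seed Integer seed; a fixed seed gives byte-identical outputs.
#' @return A validated list of class \code{simulation_config}.
#' @export
simulation_config <- function(n_group1 = 48, n_group2 = 55,
                              n_genes = 300, n_tfs = 40, n_mirnas = 40,
                              n_planted_per_category = 10,
                              effect_beta = 0.8, noise_sd = 0.5,
                              de_log2fc = 2, mirna_missing_rate = 0.02,
                              n_decoy_pairs = 200, seed = 1L) {
  cfg <- list(n_group1 = as.integer(n_group1), n_group2 = as.integer(n_group2),
              n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
              n_mirnas = as.integer(n_mirnas),
              n_planted_per_category = as.integer(n_planted_per_category),
              effect_beta = effect_beta, noise_sd = noise_sd,
              de_log2fc = de_log2fc, mirna_missing_rate = mirna_missing_rate,
              n_decoy_pairs = as.integer(n_decoy_pairs),
              seed = as.integer(seed))
  counts <- c(cfg$n_group1, cfg$n_group2, cfg$n_genes, cfg$n_tfs,
              cfg$n_mirnas, cfg$n_planted_per_category)
  if (any(counts <= 0L))
    stop("all sample/feature counts must be positive", call. = FALSE)
  if (cfg$mirna_missing_rate < 0 || cfg$mirna_missing_rate >= 1)
    stop("mirna_missing_rate must be in [0, 1)", call. = FALSE)
  if (cfg$noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (cfg$n_decoy_pairs < 0L)
    stop("n_decoy_pairs must be non-negative", call. = FALSE)
  structure(cfg, class = "simulation_config")
}

#' Read a simulation configuration from YAML
#'
#' @param path YAML file whose keys are \code{\link{simulation_config}}
#'   arguments.
#' @param seed Optional seed overriding the file's value.
#' @return A \code{simulation_config}.
#' @export
simulation_config_from_yaml <- function(path, seed = NULL) {
  args <- yaml::read_yaml(path)
  if (!is.null(seed)) args$seed <- seed
  do.call(simulation_config, args)
}

# Sign patterns of the three coherent FFL categories.  Column 2 is the
# TF<->miRNA linking edge: TF->miRNA for TRF/TAF, miRNA->TF for MRF.
ffl_sign_patterns <- list(
  TRF = c(tf_gene = -1, link = +1, mirna_gene = -1),
  TAF = c(tf_gene = +1, link = -1, mirna_gene = -1),
  MRF = c(tf_gene = +1, link = -1, mirna_gene = -1)
)

#' Simulate a two-group expression dataset with planted FFLs
#'
#' Background features are i.i.d. normal on the log2 scale (mean 6, sd 1.5).
#' For each planted FFL the driver (the TF for TRF/TAF, the miRNA for MRF) is
#' a background feature plus a group shift of \code{de_log2fc}; each directly
#' regulated member is \code{sign * effect_beta} times the driver's centred
#' profile plus Gaussian noise (\code{noise_sd}) plus its own group shift with
#' sign consistent with the coupling, so all members pass the
#' differential-expression gate.  The third pair of each triple is the
#' correlation induced through the shared driver and is recorded in
#' \code{planted_pairs} with the category's sign.  Decoy prior pairs link
#' features with independent within-group expression.  miRNA-matrix entries
#' are masked missing at \code{mirna_missing_rate}.
#'
#' The generator uses its own RNG stream seeded from \code{config$seed} and
#' restores the caller's RNG state on exit; a fixed seed gives identical
#' outputs.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return A list of class \code{ffl_simulation} with elements \code{mrna},
#'   \code{mirna} (both \code{\link{expression_matrix}}), \code{sheet},
#'   \code{pairs} (candidate prior list), \code{tf_roster}, and \code{truth}
#'   (list with \code{de_features}, \code{planted_pairs},
#'   \code{planted_ffls}).
#' @export
simulate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  k <- config$n_planted_per_category
  if (3L * k > config$n_tfs || 3L * k > config$n_mirnas ||
      3L * k > config$n_genes)
    stop("planted FFLs need 3 * n_planted_per_category features of each ",
         "kind; increase n_tfs/n_mirnas/n_genes or lower the planted count",
         call. = FALSE)

  if (exists(".Random.seed", envir = globalenv()))
    old_seed <- get(".Random.seed", envir = globalenv())
  else old_seed <- NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)

  n1 <- config$n_group1; n2 <- config$n_group2
  n <- n1 + n2
  grp1 <- c(rep(TRUE, n1), rep(FALSE, n2))
  samples <- sprintf("S%03d", seq_len(n))
  sheet <- data.frame(sample_id = samples,
                      group = ifelse(grp1, "NSE", "SE"),
                      stringsAsFactors = FALSE)

  gene_ids <- sprintf("G%04d", seq_len(config$n_genes))
  tf_ids <- sprintf("TF%03d", seq_len(config$n_tfs))
  mir_ids <- sprintf("miR-%03d", seq_len(config$n_mirnas))

  base_mu <- 6; base_sd <- 1.5
  bg <- function(nf) matrix(rnorm(nf * n, base_mu, base_sd), nf, n)
  mrna <- rbind(bg(config$n_genes), bg(config$n_tfs))
  rownames(mrna) <- c(gene_ids, tf_ids); colnames(mrna) <- samples
  mirna <- bg(config$n_mirnas)
  rownames(mirna) <- mir_ids; colnames(mirna) <- samples

  beta <- config$effect_beta; sdn <- config$noise_sd; fc <- config$de_log2fc
  categories <- c("TRF", "TAF", "MRF")
  # disjoint member pools per FFL so the truth manifest is unambiguous
  tf_pool <- matrix(tf_ids[seq_len(3L * k)], nrow = k)
  mir_pool <- matrix(mir_ids[seq_len(3L * k)], nrow = k)
  gene_pool <- matrix(gene_ids[seq_len(3L * k)], nrow = k)

  planted_pairs <- list(); planted_ffls <- list(); de <- list()
  shift <- function(d) d * fc * grp1          # group-1 minus group-2 = d * fc
  plant_member <- function(id, kind, d) {
    de[[length(de) + 1L]] <<- data.frame(feature_id = id, kind = kind,
                                         direction = if (d > 0) "up" else "down",
                                         stringsAsFactors = FALSE)
  }
  # target = own baseline + own DE shift + sign*beta*(driver centred) + noise
  couple <- function(driver_centred, s, d)
    base_mu + shift(d) + s * beta * driver_centred + rnorm(n, 0, sdn)

  for (ci in seq_along(categories)) {
    cat_name <- categories[ci]
    pat <- ffl_sign_patterns[[cat_name]]
    for (i in seq_len(k)) {
      tf <- tf_pool[i, ci]; mir <- mir_pool[i, ci]; gene <- gene_pool[i, ci]
      d_drv <- if (i %% 2L == 0L) -1 else 1     # both DE directions occur
      if (cat_name %in% c("TRF", "TAF")) {
        # TF drives both the miRNA and the gene
        z <- rnorm(n, 0, base_sd)
        mrna[tf, ] <- base_mu + shift(d_drv) + z
        mirna[mir, ] <- couple(z, pat[["link"]], pat[["link"]] * d_drv)
        mrna[gene, ] <- couple(z, pat[["tf_gene"]], pat[["tf_gene"]] * d_drv)
        plant_member(tf, "TF", d_drv)
        plant_member(mir, "miRNA", pat[["link"]] * d_drv)
        plant_member(gene, "gene", pat[["tf_gene"]] * d_drv)
        planted_pairs[[length(planted_pairs) + 1L]] <- data.frame(
          regulator_id = c(tf, tf, mir),
          regulator_class = c("TF", "TF", "miRNA"),
          target_id = c(mir, gene, gene),
          target_class = c("miRNA", "gene", "gene"),
          sign = c(pat[["link"]], pat[["tf_gene"]],
                   pat[["link"]] * pat[["tf_gene"]]),
          stringsAsFactors = FALSE)
      } else {
        # MRF chain: miRNA represses the TF, the TF activates the gene
        z <- rnorm(n, 0, base_sd)
        mirna[mir, ] <- base_mu + shift(d_drv) + z
        tf_prof <- couple(z, pat[["link"]], pat[["link"]] * d_drv)
        mrna[tf, ] <- tf_prof
        mrna[gene, ] <- couple(tf_prof - base_mu - shift(pat[["link"]] * d_drv),
                               pat[["tf_gene"]],
                               pat[["link"]] * pat[["tf_gene"]] * d_drv)
        plant_member(mir, "miRNA", d_drv)
        plant_member(tf, "TF", pat[["link"]] * d_drv)
        plant_member(gene, "gene", pat[["link"]] * pat[["tf_gene"]] * d_drv)
        planted_pairs[[length(planted_pairs) + 1L]] <- data.frame(
          regulator_id = c(mir, tf, mir),
          regulator_class = c("miRNA", "TF", "miRNA"),
          target_id = c(tf, gene, gene),
          target_class = c("TF", "gene", "gene"),
          sign = c(pat[["link"]], pat[["tf_gene"]],
                   pat[["link"]] * pat[["tf_gene"]]),
          stringsAsFactors = FALSE)
      }
      planted_ffls[[length(planted_ffls) + 1L]] <- data.frame(
        tf_id = tf, mirna_id = mir, gene_id = gene, category = cat_name,
        stringsAsFactors = FALSE)
    }
  }
  planted_pairs <- do.call(rbind, planted_pairs)
  planted_ffls <- do.call(rbind, planted_ffls)
  de_features <- do.call(rbind, de)

  # candidate prior list = planted couplings + decoys, one source tag
  prior <- data.frame(regulator_id = planted_pairs$regulator_id,
                      regulator_class = planted_pairs$regulator_class,
                      target_id = planted_pairs$target_id,
                      target_class = planted_pairs$target_class,
                      source_tag = "synthetic", stringsAsFactors = FALSE)
  planted_key <- paste(prior$regulator_id, prior$target_id, sep = "\r")
  planted_members <- de_features
  # members of one planted triple share a driver, so a pair linking them is
  # not independent: decoys must never connect two members of the same FFL
  ffl_of <- integer(0)
  for (i in seq_len(nrow(planted_ffls)))
    ffl_of[unlist(planted_ffls[i, c("tf_id", "mirna_id", "gene_id")])] <- i
  decoys <- list(); tries <- 0L
  while (length(decoys) < config$n_decoy_pairs && tries < 50L * config$n_decoy_pairs) {
    tries <- tries + 1L
    rc <- if (runif(1) < 0.5) "TF" else "miRNA"
    tc <- if (rc == "TF") sample(c("gene", "miRNA"), 1L)
          else sample(c("gene", "TF"), 1L)
    pick <- function(kind) {
      pool <- switch(kind, gene = gene_ids, TF = tf_ids, miRNA = mir_ids)
      # half the decoys connect planted (DE) members so false discoveries
      # are possible in principle, half connect background features
      sub <- planted_members$feature_id[planted_members$kind == kind]
      if (length(sub) && runif(1) < 0.5) sample(sub, 1L) else sample(pool, 1L)
    }
    reg <- pick(rc); tgt <- pick(tc)
    if (reg == tgt) next
    if (!is.na(ffl_of[reg]) && !is.na(ffl_of[tgt]) &&
        isTRUE(ffl_of[reg] == ffl_of[tgt])) next
    key <- paste(reg, tgt, sep = "\r")
    if (key %in% planted_key) next
    if (length(decoys) &&
        key %in% vapply(decoys, function(d) paste(d$regulator_id, d$target_id,
                                                  sep = "\r"), ""))
      next
    decoys[[length(decoys) + 1L]] <- data.frame(
      regulator_id = reg, regulator_class = rc, target_id = tgt,
      target_class = tc, source_tag = "synthetic", stringsAsFactors = FALSE)
  }
  prior <- rbind(prior, do.call(rbind, decoys))
  rownames(prior) <- NULL

  if (config$mirna_missing_rate > 0) {
    mask <- runif(length(mirna)) < config$mirna_missing_rate
    mirna[mask] <- NA_real_
  }

  structure(list(
    mrna = expression_matrix(mrna, "mRNA"),
    mirna = expression_matrix(mirna, "miRNA"),
    sheet = sheet,
    pairs = validate_pair_list(prior, context = "simulated priors"),
    tf_roster = tf_ids,
    truth = list(de_features = de_features,
                 planted_pairs = planted_pairs,
                 planted_ffls = planted_ffls),
    config = config), class = "ffl_simulation")
}

#' @export
print.ffl_simulation <- function(x, ...) {
  cat(sprintf("<ffl_simulation> %d + %d samples; %d mRNA, %d miRNA features; %d planted FFLs; %d prior pairs\n",
              x$config$n_group1, x$config$n_group2, nrow(x$mrna$values),
              nrow(x$mirna$values), nrow(x$truth$planted_ffls),
              nrow(x$pairs)))
  invisible(x)
}

#' Write a simulated dataset to a directory
#'
#' Emits the pipeline's on-disk formats (expression TSVs, sample sheet, prior
#' pair list, TF roster) plus the truth-manifest TSVs
#' (\code{truth_de_features.tsv}, \code{truth_planted_pairs.tsv},
#' \code{truth_planted_ffls.tsv}).
#'
#' @param sim An \code{ffl_simulation} from \code{\link{simulate_dataset}}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, \code{dir}.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "ffl_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_expression_matrix(sim$mrna, p("mrna_log2.tsv"))
  write_expression_matrix(sim$mirna, p("mirna_log2.tsv"))
  write_sample_sheet(sim$sheet, p("samples.tsv"))
  write_pair_list(sim$pairs, p("prior_pairs.tsv"))
  writeLines(sim$tf_roster, p("tf_roster.txt"))
  write.table(sim$truth$de_features, p("truth_de_features.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth$planted_pairs, p("truth_planted_pairs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth$planted_ffls, p("truth_planted_ffls.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Compare called FFLs against a planted truth manifest
#'
#' Recall is the fraction of planted FFLs recovered with the correct category;
#' precision is the fraction of called FFLs that were planted.  Both are
#' reported per category and overall.  Empty inputs give 0 with a flag
#' (\code{"no_planted"} / \code{"no_called"}) rather than NaN.
#'
#' @param truth Truth list from \code{\link{simulate_dataset}} (or any list
#'   with a \code{planted_ffls} data.frame), or the \code{planted_ffls}
#'   data.frame itself.
#' @param called_ffls FFL data.frame with columns \code{tf_id},
#'   \code{mirna_id}, \code{gene_id}, \code{category}.
#' @return A list of class \code{recovery_report} with a per-category
#'   \code{table} (rows TRF, TAF, MRF, overall) and a \code{flags} character
#'   vector.
#' @export
truth_recovery_report <- function(truth, called_ffls) {
  planted <- if (is.data.frame(truth)) truth else truth$planted_ffls
  key <- function(df) if (nrow(df))
    paste(df$tf_id, df$mirna_id, df$gene_id, df$category, sep = "\r")
  else character(0)
  pk <- key(planted); ck <- unique(key(called_ffls))
  cats <- c("TRF", "TAF", "MRF")
  row_for <- function(pk, ck, label) {
    hits <- sum(pk %in% ck)
    data.frame(category = label, n_planted = length(pk),
               n_called = length(ck), n_recovered = hits,
               recall = if (length(pk)) hits / length(pk) else 0,
               precision = if (length(ck)) sum(ck %in% pk) / length(ck) else 0,
               stringsAsFactors = FALSE)
  }
  cat_of <- function(k) sub("^.*\r", "", k)
  tab <- do.call(rbind, c(
    lapply(cats, function(cc) row_for(pk[cat_of(pk) == cc],
                                      ck[cat_of(ck) == cc], cc)),
    list(row_for(pk, ck, "overall"))))
  flags <- character(0)
  if (!length(pk)) flags <- c(flags, "no_planted")
  if (!length(ck)) flags <- c(flags, "no_called")
  structure(list(table = tab, flags = flags), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  print(x$table, row.names = FALSE)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
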