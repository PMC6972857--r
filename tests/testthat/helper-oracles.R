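# Fixture builders and independent brute-force oracles shared across tests.

# small expression matrix from a plain matrix-like spec
em <- function(values, kind = "mRNA", features = NULL, samples = NULL) {
  if (!is.matrix(values)) values <- matrix(values, nrow = length(features))
  if (!is.null(features)) rownames(values) <- features
  if (!is.null(samples)) colnames(values) <- samples
  expression_matrix(values, kind)
}

# one regulation-pair row; regulation type follows the sign of r
rp <- function(reg, rc, tgt, tc, r, p = 1e-4) {
  data.frame(regulator_id = reg, regulator_class = rc, target_id = tgt,
             target_class = tc, r = r, p = p,
             regulation_type = if (r > 0) "activation" else "repression",
             group_context = "all", stringsAsFactors = FALSE)
}

pl <- function(reg, rc, tgt, tc, src = "s1") {
  data.frame(regulator_id = reg, regulator_class = rc, target_id = tgt,
             target_class = tc, source_tag = src, stringsAsFactors = FALSE)
}

# Brute-force FFL oracle: vectorised membership test over the full
# (tf, mirna, gene) grid, independent of the join-based implementation.
brute_force_ffls <- function(reg) {
  key <- function(a, b) paste(a, b, sep = "\r")
  edge_set <- function(rc, tc, type)
    key(reg$regulator_id, reg$target_id)[
      reg$regulator_class == rc & reg$target_class == tc &
        reg$regulation_type == type]
  tfs <- unique(reg$regulator_id[reg$regulator_class == "TF"])
  tfs <- union(tfs, reg$target_id[reg$target_class == "TF"])
  mirs <- unique(c(reg$regulator_id[reg$regulator_class == "miRNA"],
                   reg$target_id[reg$target_class == "miRNA"]))
  genes <- unique(reg$target_id[reg$target_class == "gene"])
  if (!length(tfs) || !length(mirs) || !length(genes))
    return(data.frame(tf_id = character(0), mirna_id = character(0),
                      gene_id = character(0), category = character(0)))
  grid <- expand.grid(tf_id = tfs, mirna_id = mirs, gene_id = genes,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$tf_id != grid$gene_id, ]
  hit <- function(set1, set2, set3)
    key(grid$tf_id, grid$mirna_id) %in% set1 &
      key(grid$tf_id, grid$gene_id) %in% set2 &
      key(grid$mirna_id, grid$gene_id) %in% set3
  lab <- function(sub, category) {
    sub$category <- rep(category, nrow(sub))
    sub
  }
  out <- rbind(
    lab(grid[hit(edge_set("TF", "miRNA", "activation"),
                 edge_set("TF", "gene", "repression"),
                 edge_set("miRNA", "gene", "repression")), ], "TRF"),
    lab(grid[hit(edge_set("TF", "miRNA", "repression"),
                 edge_set("TF", "gene", "activation"),
                 edge_set("miRNA", "gene", "repression")), ], "TAF"),
    lab(grid[
      key(grid$mirna_id, grid$tf_id) %in% edge_set("miRNA", "TF", "repression") &
        key(grid$tf_id, grid$gene_id) %in% edge_set("TF", "gene", "activation") &
        key(grid$mirna_id, grid$gene_id) %in% edge_set("miRNA", "gene",
                                                       "repression"), ],
      "MRF"))
  rownames(out) <- NULL
  out
}

ffl_key <- function(df) sort(paste(df$tf_id, df$mirna_id, df$gene_id,
                                   df$category, sep = "|"))

# random signed edge set over small TF/miRNA/gene universes
random_edge_set <- function(n_edges = 200, n_tf = 10, n_mir = 10,
                            n_gene = 30) {
  tfs <- sprintf("T%02d", seq_len(n_tf))
  mirs <- sprintf("m%02d", seq_len(n_mir))
  genes <- sprintf("g%02d", seq_len(n_gene))
  rows <- lapply(seq_len(n_edges), function(i) {
    kind <- sample(c("tm", "tg", "mg", "mt"), 1L)
    r <- if (kind %in% c("mg", "mt")) -runif(1, 0.1, 1)
         else sample(c(-1, 1), 1L) * runif(1, 0.1, 1)
    switch(kind,
           tm = rp(sample(tfs, 1), "TF", sample(mirs, 1), "miRNA", r),
           tg = rp(sample(tfs, 1), "TF", sample(genes, 1), "gene", r),
           mg = rp(sample(mirs, 1), "miRNA", sample(genes, 1), "gene", r),
           mt = rp(sample(mirs, 1), "miRNA", sample(tfs, 1), "TF", r))
  })
  reg <- do.call(rbind, rows)
  reg[!duplicated(paste(reg$regulator_id, reg$target_id)), ]
}

# Brute-force Benjamini-Hochberg step-up
brute_force_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- rep(NA_real_, n)
  running <- Inf
  for (i in n:1) {
    running <- min(running, p[o[i]] * n / i)
    adj[o[i]] <- min(running, 1)
  }
  adj
}

# sort-and-slice hub oracle
oracle_hubs <- function(nodes, quantile) {
  k <- ceiling(quantile * nrow(nodes))
  top <- function(deg) {
    cut <- sort(deg, decreasing = TRUE)[k]
    nodes$id[deg >= cut]
  }
  sort(union(top(nodes$out_degree), top(nodes$in_degree)))
}
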