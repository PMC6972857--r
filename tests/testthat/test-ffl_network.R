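test_that("single coherent triples are classified into their category", {
  trf <- enumerate_ffls(rbind(rp("TF1", "TF", "miR1", "miRNA", 0.8),
                              rp("TF1", "TF", "g1", "gene", -0.7),
                              rp("miR1", "miRNA", "g1", "gene", -0.6)))
  expect_equal(nrow(trf), 1L)
  expect_equal(trf$category, "TRF")
  expect_equal(trf[, c("tf_id", "mirna_id", "gene_id")],
               data.frame(tf_id = "TF1", mirna_id = "miR1", gene_id = "g1"))

  # TAF and MRF share the sign pattern; with both link directions present
  # the same triple is emitted once per category
  both <- enumerate_ffls(rbind(rp("TF1", "TF", "miR1", "miRNA", -0.8),
                               rp("TF1", "TF", "g1", "gene", 0.7),
                               rp("miR1", "miRNA", "g1", "gene", -0.6),
                               rp("miR1", "miRNA", "TF1", "TF", -0.5)))
  expect_equal(sort(both$category), c("MRF", "TAF"))
  expect_equal(unique(both$tf_id), "TF1")
  # the link edge holds TF->miRNA r for TAF and miRNA->TF r for MRF
  expect_equal(both$tf_mirna_r[both$category == "TAF"], -0.8)
  expect_equal(both$tf_mirna_r[both$category == "MRF"], -0.5)
})

test_that("enumeration matches the brute-force oracle and ignores edge order", {
  set.seed(77)
  for (i in 1:25) {
    reg <- random_edge_set(n_edges = 120)
    got <- enumerate_ffls(reg)
    expect_identical(ffl_key(got), ffl_key(brute_force_ffls(reg)))
    shuffled <- reg[sample(nrow(reg)), ]
    expect_identical(enumerate_ffls(shuffled), got)
  }
})

test_that("self-regulating TF-coding genes are excluded from the gene slot", {
  reg <- rbind(rp("TF1", "TF", "miR1", "miRNA", 0.8),
               rp("TF1", "TF", "TF1", "gene", -0.7),
               rp("miR1", "miRNA", "TF1", "gene", -0.6))
  expect_equal(nrow(enumerate_ffls(reg)), 0L)
})

test_that("network assembly deduplicates shared edges and tallies degrees", {
  one <- enumerate_ffls(rbind(rp("TF1", "TF", "miR1", "miRNA", 0.8),
                              rp("TF1", "TF", "g1", "gene", -0.7),
                              rp("miR1", "miRNA", "g1", "gene", -0.6)))
  net <- build_network(one)
  expect_equal(net$stats$n_nodes, 3L)
  expect_equal(net$stats$n_edges, 3L)
  expect_equal(net$stats$n_by_class, c(TF = 1L, miRNA = 1L, gene = 1L))

  # TAF and MRF over the same triple share the TF->gene and miRNA->gene edges
  both <- enumerate_ffls(rbind(rp("TF1", "TF", "miR1", "miRNA", -0.8),
                               rp("TF1", "TF", "g1", "gene", 0.7),
                               rp("miR1", "miRNA", "g1", "gene", -0.6),
                               rp("miR1", "miRNA", "TF1", "TF", -0.5)))
  net2 <- build_network(both)
  expect_equal(net2$stats$n_edges, 4L)
  expect_equal(sum(net2$nodes$out_degree), net2$stats$n_edges)
  expect_equal(sum(net2$nodes$in_degree), net2$stats$n_edges)
  expect_equal(net2$stats$mean_total_degree, 2 * 4 / 3)

  empty <- build_network(one[0, ])
  expect_equal(empty$stats$n_nodes, 0L)
  expect_equal(empty$stats$n_edges, 0L)
})

test_that("node and link tallies match hand enumeration on a 10-FFL fixture", {
  set.seed(31)
  sim <- simulate_dataset(simulation_config(seed = 31))
  g1 <- sim$sheet$sample_id[sim$sheet$group == "NSE"]
  res <- run_ffl_pipeline(sim$mrna, sim$mirna, sim$sheet, sim$pairs,
                          group = "NSE")
  trf <- res$ffls[res$ffls$category == "TRF", ]
  net <- build_network(trf)
  truth_trf <- sim$truth$planted_ffls[sim$truth$planted_ffls$category == "TRF", ]
  # planted TRFs use disjoint members: 3 nodes and 3 edges per FFL
  expect_equal(net$stats$n_nodes, 3L * nrow(truth_trf))
  expect_equal(net$stats$n_edges, 3L * nrow(truth_trf))
  expect_equal(unname(net$stats$n_by_class),
               rep(nrow(truth_trf), 3L))
})

test_that("hub detection follows the top-quantile-with-ties rule", {
  # star: center regulates 10 leaves
  star <- do.call(rbind, lapply(1:10, function(i)
    rp("TF1", "TF", sprintf("g%02d", i), "gene", 0.9)))
  # complete the FFL structure so build_network accepts it
  star_ffls <- enumerate_ffls(rbind(star,
                                    rp("TF1", "TF", "miR1", "miRNA", -0.8),
                                    do.call(rbind, lapply(1:10, function(i)
                                      rp("miR1", "miRNA", sprintf("g%02d", i),
                                         "gene", -0.6)))))
  net <- build_network(star_ffls)
  # leaves tie at out-degree zero, so the cutoff pulls every node in
  expect_warning(hubs <- find_hubs(net, quantile = 0.2), "tied")
  expect_true("TF1" %in% hubs$node)
  expect_equal(hubs$basis[hubs$node == "TF1"], "out")
  expect_error(find_hubs(net, quantile = 1.2), "quantile")

  # cutoff ties extending to every node -> everything returned with a warning
  two <- enumerate_ffls(rbind(rp("TF1", "TF", "miR1", "miRNA", 0.8),
                              rp("TF1", "TF", "g1", "gene", -0.7),
                              rp("miR1", "miRNA", "g1", "gene", -0.6),
                              rp("TF2", "TF", "miR2", "miRNA", 0.8),
                              rp("TF2", "TF", "g2", "gene", -0.7),
                              rp("miR2", "miRNA", "g2", "gene", -0.6)))
  expect_warning(all_h <- find_hubs(build_network(two), 0.5), "tied")
  expect_equal(nrow(all_h), 6L)
})

test_that("hub selection equals a sort-and-slice oracle on random networks", {
  set.seed(55)
  for (i in 1:10) {
    reg <- random_edge_set(n_edges = 150, n_tf = 8, n_mir = 8, n_gene = 20)
    ffls <- enumerate_ffls(reg)
    if (!nrow(ffls)) next
    net <- build_network(ffls)
    q <- 0.25
    got <- suppressWarnings(find_hubs(net, q))
    expect_identical(sort(got$node), oracle_hubs(net$nodes, q))
  }
})

test_that("subtype comparison reports shared FFLs and node partitions", {
  set.seed(66)
  a <- brute_force_to_df <- enumerate_ffls(random_edge_set(200))
  expect_gt(nrow(a), 2)
  ident <- compare_subtypes(a, a)
  expect_equal(nrow(ident$shared), nrow(a))
  expect_equal(nrow(ident$a_only_nodes), 0L)

  b <- a
  b$tf_id <- paste0("X", b$tf_id)
  disj <- compare_subtypes(a, b)
  expect_equal(nrow(disj$shared), 0L)

  # fixture with known 3-FFL overlap
  b2 <- rbind(a[1:3, ], b[4:nrow(b), ])
  ov <- compare_subtypes(a, b2)
  expect_equal(nrow(ov$shared), 3L)
  expect_equal(sum(ov$shared_by_category), 3L)
})

test_that("hypergeometric upper tail matches exact pmf summation", {
  expect_equal(hypergeometric_upper(1, 1, 1, 1)$p, 1)
  expect_equal(hypergeometric_upper(0, 10, 12, 30)$p, 1)
  got <- hypergeometric_upper(7, 10, 12, 30)
  oracle <- sum(dhyper(7:10, 10, 20, 12))
  expect_equal(got$p, oracle, tolerance = 1e-12)
  expect_error(hypergeometric_upper(5, 3, 4, 10), "inconsistent")
  # extreme tail stays finite and positive in log space
  deep <- hypergeometric_upper(600, 700, 900, 10000)
  expect_true(is.finite(deep$log_p) && deep$log_p < -100)
  expect_gte(deep$p, 0)
})

test_that("FFL ranking scores by summed |r| with lexicographic ties", {
  f <- function(tf, mir, g, r1, r2, r3, cat = "TRF")
    data.frame(tf_id = tf, mirna_id = mir, gene_id = g, category = cat,
               tf_gene_r = r1, tf_gene_p = 0.01, tf_mirna_r = r2,
               tf_mirna_p = 0.01, mirna_gene_r = r3, mirna_gene_p = 0.01,
               stringsAsFactors = FALSE)
  two <- rbind(f("T2", "m1", "g1", -0.9, 0.8, -0.7),   # score 2.4
               f("T1", "m1", "g2", -0.6, 0.6, -0.6))   # score 1.8
  top <- suppressWarnings(rank_ffls(two, k = 5))
  expect_equal(top$tf_id, c("T2", "T1"))

  tie <- rbind(f("T2", "m1", "g1", -0.5, 0.5, -0.5),
               f("T1", "m1", "g1", -0.5, 0.5, -0.5))
  expect_equal(suppressWarnings(rank_ffls(tie, 5))$tf_id, c("T1", "T2"))
  expect_warning(rank_ffls(two, k = 5), "only 2")

  set.seed(88)
  many <- do.call(rbind, lapply(1:20, function(i)
    f(sprintf("T%02d", i), "m1", "g1", -runif(1), runif(1), -runif(1))))
  got <- rank_ffls(many, 5)
  score <- abs(many$tf_gene_r) + abs(many$tf_mirna_r) + abs(many$mirna_gene_r)
  oracle <- many$tf_id[order(-score, many$tf_id)][1:5]
  expect_equal(got$tf_id, oracle)
})

test_that("ffl tally totals per-category counts", {
  tly <- ffl_tally(c(TRF = 10, TAF = 25, MRF = 5))
  expect_equal(tly$total, 40)
  expect_equal(tly$taf_pct, 62.5)
})
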