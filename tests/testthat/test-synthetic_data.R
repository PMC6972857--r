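test_that("a fixed seed gives byte-identical simulated datasets", {
  cfg <- simulation_config(seed = 11)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a[names(a) != "config"], b[names(b) != "config"])

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(a, d1)
  write_simulation(b, d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  expect_identical(unname(tools::md5sum(file.path(d1, f1))),
                   unname(tools::md5sum(file.path(d2, f2))))
})

test_that("zero noise makes every planted direct pair perfectly correlated within group", {
  sim <- simulate_dataset(simulation_config(noise_sd = 0, seed = 3,
                                            mirna_missing_rate = 0))
  g1 <- sim$sheet$sample_id[sim$sheet$group == "NSE"]
  val <- function(id) {
    if (id %in% feature_ids(sim$mirna)) sim$mirna$values[id, g1]
    else sim$mrna$values[id, g1]
  }
  pp <- sim$truth$planted_pairs
  # direct pairs are driver->target couplings; the induced miRNA-gene (or
  # TF-gene chain) pairs are also noise-free here, so all planted |r| = 1
  for (i in seq_len(nrow(pp))) {
    r <- cor(val(pp$regulator_id[i]), val(pp$target_id[i]))
    expect_equal(abs(r), 1, tolerance = 1e-10)
    expect_equal(sign(r), pp$sign[i])
  }
})

test_that("planted within-group correlations match a Monte-Carlo oracle of the model", {
  cfg <- simulation_config(n_group1 = 50, n_group2 = 50, effect_beta = 0.8,
                           noise_sd = 0.5, seed = 7, mirna_missing_rate = 0)
  sim <- simulate_dataset(cfg)
  g1 <- sim$sheet$sample_id[sim$sheet$group == "NSE"]
  val <- function(id) {
    if (id %in% feature_ids(sim$mirna)) sim$mirna$values[id, g1]
    else sim$mrna$values[id, g1]
  }
  pp <- sim$truth$planted_pairs
  observed <- mean(vapply(seq_len(nrow(pp)), function(i)
    abs(cor(val(pp$regulator_id[i]), val(pp$target_id[i]))), numeric(1)))

  # Independent oracle: re-draws the generative model (driver z ~ N(0,1.5^2);
  # TRF/TAF triple = two couplings off one driver, MRF = a chain) and
  # averages |r| over the same mix of pair types, 200 replicates at n = 50.
  set.seed(990)
  beta <- 0.8; sdn <- 0.5; n <- 50
  reps <- replicate(200, {
    z <- rnorm(n, 0, 1.5)
    a <- beta * z + rnorm(n, 0, sdn)      # first coupled member
    b <- beta * z + rnorm(n, 0, sdn)      # second member off the driver
    chain <- beta * a + rnorm(n, 0, sdn)  # chain member (MRF gene)
    c(direct1 = abs(cor(z, a)), direct2 = abs(cor(z, b)),
      induced = abs(cor(a, b)),
      chain_direct = abs(cor(a, chain)), chain_induced = abs(cor(z, chain)))
  })
  m <- rowMeans(reps)
  # planted pairs per TRF/TAF FFL: 2 direct + 1 induced; per MRF FFL:
  # direct (miR->TF), chain direct (TF->gene), chain induced (miR->gene)
  oracle <- (2 * (m[["direct1"]] + m[["direct2"]] + m[["induced"]]) / 3 +
               (m[["direct1"]] + m[["chain_direct"]] + m[["chain_induced"]]) / 3) / 3
  expect_lt(abs(observed - oracle), 0.05)
})

test_that("planted structure is internally consistent and priors cover it", {
  sim <- simulate_dataset(simulation_config(seed = 5))
  pp <- sim$truth$planted_pairs
  ffl <- sim$truth$planted_ffls
  pk <- paste(pp$regulator_id, pp$target_id)
  for (i in seq_len(nrow(ffl))) {
    cat <- ffl$category[i]
    link <- if (cat == "MRF") paste(ffl$mirna_id[i], ffl$tf_id[i])
            else paste(ffl$tf_id[i], ffl$mirna_id[i])
    expect_true(all(c(link,
                      paste(ffl$tf_id[i], ffl$gene_id[i]),
                      paste(ffl$mirna_id[i], ffl$gene_id[i])) %in% pk))
  }
  prior_key <- paste(sim$pairs$regulator_id, sim$pairs$target_id)
  expect_true(all(pk %in% prior_key))
  # planted FFL members are planted differentially expressed
  expect_true(all(unlist(ffl[, c("tf_id", "mirna_id", "gene_id")]) %in%
                    sim$truth$de_features$feature_id))
})

test_that("over-requested planted FFLs raise an error", {
  expect_error(simulate_dataset(simulation_config(n_tfs = 5,
                                                  n_planted_per_category = 10)),
               "planted")
})

test_that("recovery report arithmetic: perfect, empty and partial calls", {
  planted <- data.frame(tf_id = sprintf("T%d", 1:10),
                        mirna_id = sprintf("m%d", 1:10),
                        gene_id = sprintf("g%d", 1:10),
                        category = rep(c("TRF", "TAF"), 5),
                        stringsAsFactors = FALSE)
  perfect <- truth_recovery_report(planted, planted)
  expect_equal(perfect$table$recall, rep(c(1, 1, 0, 1), c(1, 1, 1, 1)))
  expect_equal(perfect$table$precision[perfect$table$category == "overall"], 1)

  none <- truth_recovery_report(planted, planted[0, ])
  expect_equal(none$table$recall[none$table$category == "overall"], 0)
  expect_equal(none$table$precision[none$table$category == "overall"], 0)
  expect_true("no_called" %in% none$flags)

  decoys <- data.frame(tf_id = c("TX", "TY"), mirna_id = c("mX", "mY"),
                       gene_id = c("gX", "gY"), category = "TRF",
                       stringsAsFactors = FALSE)
  part <- truth_recovery_report(planted, rbind(planted[1:8, ], decoys))
  ov <- part$table[part$table$category == "overall", ]
  expect_equal(ov$recall, 0.8)
  expect_equal(ov$precision, 0.8)
})

test_that("simulation config round-trips through YAML with seed override", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_group1: 20", "n_group2: 25", "effect_beta: 0.9",
               "seed: 4"), path)
  cfg <- simulation_config_from_yaml(path)
  expect_equal(cfg$n_group1, 20L)
  expect_equal(cfg$effect_beta, 0.9)
  expect_equal(simulation_config_from_yaml(path, seed = 99)$seed, 99L)
})
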