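test_that("gene filter applies the strict more-than-half rule", {
  m <- em(rbind(c(0.5, 0.2, 3.0, 0.1),    # 75% below 1 -> removed
                c(0.5, 0.5, 3.0, 3.0),    # exactly 50% below -> retained
                c(2.0, 1.0, 3.0, 5.0)),   # none below -> retained
          features = c("gA", "gB", "gC"), samples = paste0("s", 1:4))
  out <- filter_genes(m)
  expect_setequal(feature_ids(out), c("gB", "gC"))
  # idempotent
  expect_identical(filter_genes(out)$values, out$values)
})

test_that("miRNA filter applies missingness and strict above-threshold rules", {
  v <- matrix(5, 3, 10, dimnames = list(c("mA", "mB", "mC"), paste0("s", 1:10)))
  v["mA", 1:2] <- NA            # 20% missing -> removed
  v["mB", ] <- c(4, 4, rep(1, 8))  # above 3.46 in 2/10 -> retained
  v["mC", ] <- c(4, rep(1, 9))     # above in exactly 10%, not more -> removed
  out <- filter_mirnas(em(v, "miRNA"))
  expect_identical(feature_ids(out), "mB")
  expect_identical(filter_mirnas(out)$values, out$values)
})

test_that("log2 fold-change is the difference of group means with matching direction", {
  v <- rbind(c(8, 8, 8, 6, 6, 6), c(3, 3, 3, 7, 7, 7))
  m <- em(v, features = c("up2", "down4"), samples = paste0("s", 1:6))
  sheet <- data.frame(sample_id = paste0("s", 1:6),
                      group = rep(c("A", "B"), each = 3))
  de <- differential_expression(m, sheet,
                                prior = list(d0 = 4, s02 = 0.05))
  expect_equal(de$log2fc, c(2, -4))
  expect_equal(de$direction, c("up", "down"))
  expect_true(all(de$p_adj >= de$p_raw))
})

test_that("with d0 = 0 the moderated t reduces to the pooled two-sample t", {
  set.seed(42)
  v <- matrix(rnorm(20 * 10, 6, 1), 20, 10,
              dimnames = list(sprintf("f%02d", 1:20), paste0("s", 1:10)))
  m <- em(v)
  sheet <- data.frame(sample_id = paste0("s", 1:10),
                      group = rep(c("A", "B"), each = 5))
  de <- differential_expression(m, sheet, prior = list(d0 = 0, s02 = 1))
  # hand-computed pooled t for each feature
  pooled_t <- apply(v, 1, function(x) {
    x1 <- x[1:5]; x2 <- x[6:10]
    sp2 <- (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)) / 8
    (mean(x1) - mean(x2)) / sqrt(sp2 * (1 / 5 + 1 / 5))
  })
  expect_equal(de$t, unname(pooled_t), tolerance = 1e-12)
})

test_that("moderated statistics agree with the limma reference implementation", {
  skip_if_not_installed("limma")
  set.seed(7)
  n1 <- 9; n2 <- 11
  v <- matrix(rnorm(150 * (n1 + n2), 0, 1), 150,
              dimnames = list(sprintf("f%03d", 1:150),
                              sprintf("s%02d", 1:(n1 + n2))))
  # heterogeneous true variances so the prior df is finite and shrinkage real
  v <- 6 + v * sqrt(1 / stats::rchisq(150, df = 5))
  v[1:10, 1:n1] <- v[1:10, 1:n1] + 2
  m <- em(v)
  sheet <- data.frame(sample_id = colnames(v),
                      group = rep(c("A", "B"), c(n1, n2)))
  de <- differential_expression(m, sheet)

  design <- cbind(1, rep(c(1, 0), c(n1, n2)))
  fit <- limma::eBayes(limma::lmFit(v, design))
  expect_equal(de$log2fc, unname(fit$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(attr(de, "prior")$d0, fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(de, "prior")$s02, fit$s2.prior, tolerance = 1e-6)
  expect_equal(de$t, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(de$p_raw, unname(fit$p.value[, 2]), tolerance = 1e-8)
})

test_that("BH adjustment matches a brute-force step-up and preserves p-value ranking", {
  set.seed(123)
  for (n in c(1, 7, 50, 100)) {
    p <- runif(n)
    expect_equal(p.adjust(p, "BH"), brute_force_bh(p), tolerance = 1e-12)
  }
  p <- runif(100)
  adj <- p.adjust(p, "BH")
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
})

test_that("DE calling applies the inclusive fold-change and strict p rules", {
  rec <- data.frame(feature_id = c("a", "b", "c"),
                    log2fc = c(1.0, 3.0, -1.5),
                    t = 0, p_raw = 0.01,
                    p_adj = c(0.04, 0.06, 0.01),
                    direction = c("up", "up", "down"),
                    stringsAsFactors = FALSE)
  called <- call_de(rec)
  expect_setequal(called$feature_id, c("a", "c"))
  empty <- call_de(rec[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("direction concordance counts shared sign patterns", {
  de_tab <- function(ids, fc)
    data.frame(feature_id = ids, log2fc = fc, stringsAsFactors = FALSE)
  conc <- direction_concordance(de_tab("x", 2), de_tab("x", 0.5))
  expect_equal(conc$fraction, 1)
  disc <- direction_concordance(de_tab("x", 2), de_tab("x", -1))
  expect_equal(disc$fraction, 0)
  expect_warning(none <- direction_concordance(de_tab("x", 2),
                                               de_tab("y", 1)),
                 "no shared")
  expect_equal(none$n_shared, 0L)
})

test_that("DE on planted features recovers the truth with controlled false positives", {
  sim <- simulate_dataset(simulation_config(n_group1 = 50, n_group2 = 50,
                                            seed = 21))
  fm <- filter_genes(sim$mrna)
  fmi <- filter_mirnas(sim$mirna)
  called <- rbind(call_de(differential_expression(fm, sim$sheet)),
                  call_de(differential_expression(fmi, sim$sheet)))
  truth <- sim$truth$de_features
  recall <- mean(truth$feature_id %in% called$feature_id)
  expect_gte(recall, 0.95)
  # direction agrees with the planted direction
  hit <- merge(truth, called, by = "feature_id")
  expect_true(all(hit$direction.x == hit$direction.y))
  nulls <- setdiff(c(feature_ids(fm), feature_ids(fmi)), truth$feature_id)
  fp <- mean(nulls %in% called$feature_id)
  expect_lte(fp, 0.05)
})
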