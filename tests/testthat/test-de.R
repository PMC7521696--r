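# Differential-expression core: normalization, QC, NB Wald contrast,
# BH adjustment, DEG calling, ddCt.

test_that("size factors: identity, scale equivariance, brute-force agreement", {
  m <- matrix(5L, 20, 3, dimnames = list(paste0("g", 1:20), paste0("s", 1:3)))
  expect_equal(unname(size_factors(m)), rep(1, 3))

  set.seed(1)
  base <- matrix(rpois(200 * 3, 50), 200, 3,
                 dimnames = list(paste0("g", 1:200), paste0("s", 1:3)))
  doubled <- base
  doubled[, 2] <- base[, 2] * 2L
  sf <- size_factors(doubled)
  expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 0.05)

  # brute-force median-of-ratios oracle
  set.seed(2)
  x <- matrix(rpois(500 * 4, 30) + 1L, 500, 4,
              dimnames = list(paste0("g", 1:500), paste0("s", 1:4)))
  ref <- exp(rowMeans(log(x)))
  raw <- apply(x, 2, function(col) median(col / ref))
  expect_equal(unname(size_factors(x)), unname(raw / exp(mean(log(raw)))))

  allz <- matrix(c(0L, 1L, 1L, 0L), 2, 2,
                 dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(size_factors(allz), "CPM")
})

test_that("replicate QC retains correlated replicates and drops noise", {
  sim <- small_sim(n_genes = 800, seed = 21, fractions = c(additive = 0))
  keep <- qc_replicates(sim$counts, sim$design, min_corr = 0.8)
  expect_setequal(keep, sim$design$sample_id)  # clean replicates retained

  # corrupt one replicate with independent noise
  counts <- sim$counts
  bad <- "4x_hybrid_meiosis_r3"
  set.seed(5)
  counts[, bad] <- rpois(nrow(counts), 2^7)   # no gene-level structure
  expect_warning(keep2 <- qc_replicates(counts, sim$design, min_corr = 0.8),
                 "dropping")
  expect_false(bad %in% keep2)
  expect_setequal(setdiff(sim$design$sample_id, bad), keep2)

  # min_corr = 0 retains everything
  expect_setequal(qc_replicates(counts, sim$design, min_corr = 0),
                  sim$design$sample_id)
})

test_that("contrast on identical groups gives log2fc 0 and large p", {
  m <- matrix(rep(c(40L, 80L, 120L), each = 6), 3, 6, byrow = TRUE,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:6)))
  d <- data.frame(sample_id = paste0("s", 1:6), ploidy = "2x",
                  role = rep(c("hybrid", "maternal"), each = 3),
                  stage = "meiosis", replicate = rep(1:3, 2))
  res <- test_contrast(m, d, list(role = "hybrid"), list(role = "maternal"))
  expect_equal(res$log2fc, rep(0, 3))
  expect_true(all(res$p_raw > 0.9))
})

test_that("null simulation holds the type-I error near nominal", {
  sim <- generate_experiment(sim_config(n_genes = 4000, stages = "meiosis",
                                        ploidies = "4x",
                                        pattern_fractions = c(additive = 0),
                                        seed = 31))
  res <- test_contrast(sim$counts, sim$design, list(role = "hybrid"),
                       list(role = "maternal"))
  frac <- mean(res$p_raw[res$tested] < 0.05)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.08)
})

test_that("planted 4-fold changes are recovered with q <= 0.05", {
  # 200 independent planted genes stand in for 200 simulation replicates
  sim <- generate_experiment(sim_config(
    n_genes = 2000, stages = "meiosis", ploidies = "4x", dispersion = 0.05,
    pattern_fractions = c(transgressive_up = 0.1), effect_log2fc = 2,
    seed = 41))
  res <- test_contrast(sim$counts, sim$design, list(role = "hybrid"),
                       list(role = "maternal"))
  planted <- sim$truth$gene_id[sim$truth$group == "transgressive_up"]
  q <- res$q_fdr[match(planted, res$gene_id)]
  expect_gte(mean(q <= 0.05, na.rm = TRUE), 0.95)
})

test_that("BH adjustment matches the step-up formula and brute force", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.1, NA)), "NA")
  set.seed(8)
  for (n in c(1, 10, 1000)) {
    p <- runif(n)^2
    expect_equal(bh_adjust(p), bh_brute(p))
  }
})

test_that("DEG calling uses inclusive dual bounds and is threshold-monotone", {
  res <- data.frame(gene_id = c("a", "b", "c", "d"),
                    mean_a = 1, mean_b = 1,
                    log2fc = c(1.0, 0.9, -1.4, 3.0),
                    p_raw = c(0.001, 0.0001, 0.002, 0.2),
                    q_fdr = c(0.05, 0.001, 0.01, 0.3),
                    tested = TRUE)
  calls <- call_degs(res, deg_thresholds(2, 0.05))
  expect_setequal(calls$gene_id, c("a", "c"))  # exact bounds are called
  expect_equal(calls$direction[calls$gene_id == "c"], "down")

  # relaxing either threshold never removes a call
  set.seed(9)
  rnd <- data.frame(gene_id = paste0("g", 1:300), mean_a = 1, mean_b = 1,
                    log2fc = rnorm(300, 0, 2), p_raw = runif(300),
                    q_fdr = runif(300), tested = TRUE)
  strict <- call_degs(rnd, deg_thresholds(2, 0.05))$gene_id
  expect_true(all(strict %in% call_degs(rnd, deg_thresholds(1.5, 0.05))$gene_id))
  expect_true(all(strict %in% call_degs(rnd, deg_thresholds(2, 0.2))$gene_id))
})

test_that("2^-ddCt relative expression follows the closed form", {
  expect_equal(relative_expression_ddct(20, 20, 20, 20), 1)
  expect_equal(relative_expression_ddct(19, 20, 20, 20), 2)
  expect_equal(relative_expression_ddct(20, 18, 24, 18), 16)
  expect_error(relative_expression_ddct(NA, 1, 1, 1), "finite")
})

test_that("all-zero genes are excluded from testing and the BH family", {
  m <- matrix(c(0L, 0L, 0L, 0L, 5L, 6L, 7L, 8L), 2, 4, byrow = TRUE,
              dimnames = list(c("z", "g"), paste0("s", 1:4)))
  m <- rbind(m, g2 = c(10L, 12L, 30L, 28L))
  d <- data.frame(sample_id = paste0("s", 1:4), ploidy = "2x",
                  role = rep(c("hybrid", "maternal"), each = 2),
                  stage = "meiosis", replicate = rep(1:2, 2))
  res <- test_contrast(m, d, list(role = "hybrid"), list(role = "maternal"))
  expect_false(res$tested[res$gene_id == "z"])
  expect_true(is.na(res$p_raw[res$gene_id == "z"]))
  expect_false("z" %in% call_degs(res)$gene_id)
})
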