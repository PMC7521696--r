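# Synthetic experiment generator: determinism, planted-pattern bookkeeping,
# mean/variance structure.

test_that("identical config gives byte-identical output and no global RNG leak", {
  cfg <- sim_config(n_genes = 120, seed = 42)
  set.seed(999)
  before <- .Random.seed
  a <- generate_experiment(cfg)
  expect_identical(.Random.seed, before)  # caller RNG state untouched
  b <- generate_experiment(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$design, b$design)
  expect_identical(a$truth, b$truth)
})

test_that("all-zero fractions give only conserved genes with equal true means", {
  cfg <- sim_config(n_genes = 80, pattern_fractions = c(additive = 0),
                    seed = 3)
  sim <- generate_experiment(cfg)
  expect_true(all(sim$truth$group == "conserved"))
  expect_equal(sim$truth$log2_mean_maternal, sim$truth$log2_mean_hybrid)
  expect_equal(sim$truth$log2_mean_paternal, sim$truth$log2_mean_hybrid)
})

test_that("pattern assignment follows the seeded shuffle in contiguous blocks", {
  cfg <- sim_config(n_genes = 2000,
                    pattern_fractions = c(transgressive_up = 0.05),
                    seed = 17)
  sim <- generate_experiment(cfg)
  expect_equal(sum(sim$truth$group == "transgressive_up"), 100)
  # independent re-computation of the seeded shuffle
  set.seed(17)
  perm <- sample.int(2000)
  expect_setequal(which(sim$truth$group == "transgressive_up"), perm[1:100])
})

test_that("planted true means realize each pattern at exactly the effect size", {
  sim <- small_sim(n_genes = 600, seed = 5)
  tr <- sim$truth
  e <- 2
  hi <- pmax(tr$log2_mean_maternal, tr$log2_mean_paternal)
  lo <- pmin(tr$log2_mean_maternal, tr$log2_mean_paternal)
  f1 <- tr$log2_mean_hybrid
  i <- tr$group == "transgressive_up"
  expect_equal(f1[i], hi[i] + e)             # above both parents by e
  i <- tr$group == "transgressive_down"
  expect_equal(f1[i], lo[i] - e)
  i <- tr$group == "additive"
  expect_equal(f1[i], (hi[i] + lo[i]) / 2)   # geometric mid-parent
  expect_equal(hi[i] - f1[i], rep(e, sum(i)))
  i <- tr$group == "hp_eld"
  expect_equal(f1[i], hi[i]); expect_equal(hi[i] - lo[i], rep(e, sum(i)))
  i <- tr$group == "lp_eld"
  expect_equal(f1[i], lo[i]); expect_equal(hi[i] - lo[i], rep(e, sum(i)))
})

test_that("simulated counts follow the NB mean/variance law", {
  # one gene, many replicates: Var ~= mu + phi mu^2 within sampling tolerance
  cfg <- sim_config(n_genes = 4, n_replicates = 2000, stages = "meiosis",
                    ploidies = "2x", baseline_log_mean = 8,
                    baseline_log_sd = 0, dispersion = 0.2, libsize_cv = 0,
                    pattern_fractions = c(additive = 0), seed = 7)
  sim <- generate_experiment(cfg)
  x <- sim$counts[, sim$design$role == "hybrid"]
  mu <- 2^8; v_theory <- mu + 0.2 * mu^2
  v_emp <- apply(x, 1, var)
  # NB variance-of-variance tolerance: allow 15% relative deviation at n=2000
  expect_true(all(abs(v_emp / v_theory - 1) < 0.15))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(100, dispersion = 0), "dispersion")
  expect_error(sim_config(100, pattern_fractions = c(additive = 0.7,
                                                     hp_eld = 0.6)),
               "sum")
  expect_error(sim_config(100, pattern_fractions = c(bogus = 0.1)),
               "unknown")
  expect_error(sim_config(100, effect_log2fc = 0.5), "effect_log2fc")
})

test_that("annotation and QTL generators respect bounds and determinism", {
  a1 <- generate_annotation(50, n_chromosomes = 3, chrom_length = 1e5,
                            seed = 9)
  a2 <- generate_annotation(50, n_chromosomes = 3, chrom_length = 1e5,
                            seed = 9)
  expect_identical(a1, a2)
  expect_true(all(a1$start < a1$end))
  expect_true(all(a1$start >= 0 & a1$end <= 1e5))
  one <- generate_annotation(1, seed = 1)
  expect_equal(nrow(one), 1)
  expect_lt(one$start, one$end)
  expect_error(generate_annotation(5, chrom_length = 100), "too small")

  q <- generate_qtls("1000-grain weight", 5, seed = 2)
  expect_equal(nrow(q), 5)
  expect_true(all(q$trait == "1000-grain weight"))
  expect_identical(q, generate_qtls("1000-grain weight", 5, seed = 2))
  expect_equal(nrow(generate_qtls(character(), 5)), 0)
})

test_that("cytology counts are binomial draws at the requested rate", {
  expect_equal(generate_cytology_counts(1, 50, seed = 1)$normal, 50)
  expect_equal(generate_cytology_counts(0, 50, seed = 1)$normal, 0)
  cc <- generate_cytology_counts(0.8, 10000, seed = 4)
  se3 <- 3 * sqrt(0.8 * 0.2 / 10000)
  expect_lt(abs(cc$normal / cc$total - 0.8), se3)
})
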