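# Twelve-pattern dominance classification, group summaries and candidates.

test_that("definition-forced single-gene classifications", {
  # hybrid above both parents, parents equal
  expect_equal(classify_gene("+", "+", "0")$group, "transgressive_up")
  # hybrid differs from both parents in opposite directions, parents differ
  expect_equal(classify_gene("-", "+", "-")$group, "additive")
  # hybrid equals parent 1, above parent 2, parent 1 the higher parent
  expect_equal(classify_gene("0", "+", "+", 10, 2)$group, "hp_eld")
  # hybrid equals the low parent, below the high one
  expect_equal(classify_gene("-", "0", "+", 10, 2)$group, "lp_eld")
  # hybrid below both
  expect_equal(classify_gene("-", "-", "-")$group, "transgressive_down")
  # nothing significant
  expect_equal(classify_gene("0", "0", "0")$group, "unclassified")
  expect_error(classify_gene("x", "0", "0"), "calls")
})

test_that("the 27 call combinations map to exactly one group each and yield 12 patterns", {
  calls <- c("+", "-", "0")
  combos <- expand.grid(f1_p1 = calls, f1_p2 = calls, p1_p2 = calls,
                        stringsAsFactors = FALSE)
  seen <- data.frame()
  for (i in seq_len(nrow(combos))) {
    # both parent-mean orderings consistent with the parent call
    means <- switch(combos$p1_p2[i],
                    "+" = list(c(10, 2)),
                    "-" = list(c(2, 10)),
                    "0" = list(c(10, 2), c(2, 10)))
    for (m in means) {
      out <- classify_gene(combos$f1_p1[i], combos$f1_p2[i],
                           combos$p1_p2[i], m[1], m[2])
      expect_length(out$group, 1)        # total function: exactly one group
      expect_true(out$group %in% c("additive", "hp_eld", "lp_eld",
                                   "transgressive_up", "transgressive_down",
                                   "unclassified"))
      expect_equal(is.na(out$pattern), out$group == "unclassified")
      seen <- rbind(seen, data.frame(pattern = out$pattern,
                                     group = out$group))
    }
  }
  pats <- unique(seen[!is.na(seen$pattern), ])
  expect_equal(nrow(pats), 12)           # exactly twelve patterns realized
  tab <- table(pats$group)
  expect_equal(setNames(as.integer(tab), names(tab))[
                 c("additive", "hp_eld", "lp_eld", "transgressive_up",
                   "transgressive_down")],
               c(additive = 2L, hp_eld = 2L, lp_eld = 2L,
                 transgressive_up = 3L, transgressive_down = 3L))
  # patterns are exclusive: each pattern belongs to a single group
  expect_equal(anyDuplicated(pats$pattern), 0)
})

test_that("classification is invariant under parent relabeling", {
  calls <- c("+", "-", "0")
  flip <- c("+" = "-", "-" = "+", "0" = "0")
  combos <- expand.grid(a = calls, b = calls, p = calls,
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    g1 <- classify_gene(combos$a[i], combos$b[i], combos$p[i])$group
    g2 <- classify_gene(combos$b[i], combos$a[i],
                        flip[[combos$p[i]]])$group
    expect_equal(g1, g2)
  }
})

test_that("classify_all recovers planted groups on a powered simulation", {
  sim <- small_sim(n_genes = 1200, seed = 23, dispersion = 0.05, effect = 2)
  fit <- polyhet(sim$counts, sim$design, qc = FALSE)
  cs <- fit$contrasts[["4x:meiosis"]]
  fam <- fit$families[["4x:meiosis"]]
  dom <- classify_all(fam$degs_hp, cs$f1_maternal, cs$f1_paternal, cs$pp)
  expect_setequal(dom$gene_id, fam$degs_hp)   # only DEGs_HP classified
  truth <- setNames(sim$truth$group, sim$truth$gene_id)
  cl <- dom[dom$group != "unclassified", ]
  acc <- mean(truth[cl$gene_id] == cl$group)
  expect_gte(acc, 0.9)
  # group-wise confusion is near-diagonal
  tab <- table(truth[cl$gene_id], cl$group)
  shared <- intersect(rownames(tab), colnames(tab))
  offdiag <- 1 - sum(diag(tab[shared, shared])) / sum(tab)
  expect_lt(offdiag, 0.1)
})

test_that("an all-null simulation classifies (near) nothing", {
  sim <- generate_experiment(sim_config(n_genes = 1000, stages = "meiosis",
                                        ploidies = "4x",
                                        pattern_fractions = c(additive = 0),
                                        seed = 29))
  fit <- polyhet(sim$counts, sim$design, qc = FALSE)
  expect_lte(nrow(fit$dominance[["meiosis"]]), 10)  # FDR-level leakage only
})

test_that("classify_all demands complete contrast coverage", {
  sim <- small_sim(n_genes = 100, seed = 3)
  fit <- polyhet(sim$counts, sim$design, qc = FALSE)
  cs <- fit$contrasts[["4x:meiosis"]]
  short <- cs$pp[-1, ]
  expect_error(classify_all(cs$pp$gene_id[1], cs$f1_maternal,
                            cs$f1_paternal, short), "missing")
})

test_that("summaries reproduce printed-style counts and percentages", {
  counts <- c(additive = 24, hp_eld = 107, lp_eld = 198,
              transgressive_down = 549, transgressive_up = 26)
  calls <- data.frame(
    gene_id = paste0("g", seq_len(sum(counts))),
    pattern = "I",
    group = rep(names(counts), counts), stringsAsFactors = FALSE)
  s <- summarize_dominance(calls)
  expect_equal(attr(s, "n_classified"), 904L)
  got <- setNames(s$percent, s$group)
  expect_equal(got[["additive"]], 2.65)
  expect_equal(got[["hp_eld"]], 11.84)
  expect_equal(got[["lp_eld"]], 21.90)
  expect_equal(got[["transgressive_down"]], 60.73)
  expect_equal(got[["transgressive_up"]], 2.88)
  expect_lt(abs(sum(s$percent) - 100), 0.05)
  expect_length(heterosis_candidates(calls), 133)

  counts2 <- c(additive = 21, hp_eld = 37, lp_eld = 4,
               transgressive_down = 2, transgressive_up = 4)
  calls2 <- data.frame(gene_id = paste0("h", seq_len(sum(counts2))),
                       pattern = "I", group = rep(names(counts2), counts2),
                       stringsAsFactors = FALSE)
  s2 <- summarize_dominance(calls2)
  expect_equal(setNames(s2$percent, s2$group)[["additive"]], 30.88)
  expect_length(heterosis_candidates(calls2), 41)

  one <- data.frame(gene_id = "g", pattern = "VII",
                    group = "transgressive_up")
  expect_equal(summarize_dominance(one)$percent[
    summarize_dominance(one)$group == "transgressive_up"], 100)
  expect_equal(attr(summarize_dominance(calls[0, ]), "n_classified"), 0L)
})

test_that("cross-stage candidate intersection behaves as a set intersection", {
  expect_setequal(cross_stage_common(c("a", "b"), c("b", "c")), "b")
  expect_length(cross_stage_common("a", "b"), 0)
  expect_setequal(cross_stage_common(c("a", "b"), c("a", "b")), c("a", "b"))
})
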