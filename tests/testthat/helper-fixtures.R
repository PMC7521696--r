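# Shared fixtures built in code.

small_sim <- function(n_genes = 400, seed = 11, dispersion = 0.05,
                      effect = 2,
                      fractions = c(additive = 0.06, hp_eld = 0.06,
                                    lp_eld = 0.06, transgressive_up = 0.06,
                                    transgressive_down = 0.06)) {
  generate_experiment(sim_config(n_genes = n_genes, dispersion = dispersion,
                                 effect_log2fc = effect,
                                 pattern_fractions = fractions, seed = seed))
}

# brute-force BH step-up, independent of stats::p.adjust
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}

# brute-force hypergeometric upper tail from the PMF via choose()
hyper_upper_brute <- function(k, K, n, N) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# all-pairs interval overlap oracle on 0-based half-open intervals
overlap_brute <- function(genes, qtls) {
  out <- list()
  for (i in seq_len(nrow(genes))) for (j in seq_len(nrow(qtls))) {
    if (genes$chrom[i] != qtls$chrom[j]) next
    ov <- min(genes$end[i], qtls$end[j]) - max(genes$start[i], qtls$start[j])
    if (ov >= 1)
      out[[length(out) + 1L]] <- data.frame(
        gene_id = genes$gene_id[i], qtl_id = qtls$qtl_id[j],
        trait = qtls$trait[j], overlap_bp = as.integer(ov),
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(gene_id = character(), qtl_id = character(),
                      trait = character(), overlap_bp = integer()))
  d <- do.call(rbind, out)
  d <- d[order(d$trait, d$qtl_id, d$gene_id), ]
  rownames(d) <- NULL
  d
}
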