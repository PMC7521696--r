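# Synthetic data generation: NB count matrices with planted dominance
# patterns, gene/QTL interval sets, and cytology cell counts.

#' Simulation configuration
#'
#' Builds and validates the configuration for [generate_experiment()]. The
#' defaults emulate a two-ploidy, two-stage anther RNA-seq design with three
#' biological replicates per (ploidy, role, stage) group.
#'
#' @param n_genes number of genes to simulate.
#' @param n_replicates replicates per (ploidy, role, stage) group.
#' @param stages stage labels (default meiosis and single microspore).
#' @param ploidies ploidy labels (default diploid "2x" and autotetraploid "4x").
#' @param baseline_log_mean,baseline_log_sd mean and SD of per-gene baseline
#'   expression on the log2 scale.
#' @param dispersion negative-binomial dispersion phi, so that
#'   Var = mu + phi * mu^2.
#' @param libsize_cv coefficient of variation of log-normal library-size
#'   factors (renormalised to geometric mean 1), in `[0, 1)`.
#' @param pattern_fractions named numeric vector of fractions of genes planted
#'   in each dominance group; names from `additive`, `hp_eld`, `lp_eld`,
#'   `transgressive_up`, `transgressive_down`. Fractions must sum to at most
#'   1; the remainder are conserved (no planted effect).
#' @param effect_log2fc planted absolute log2 fold change for every
#'   significant pairwise difference among parent/hybrid group means; must be
#'   >= 1.
#' @param seed integer RNG seed.
#' @return a validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes,
                       n_replicates = 3L,
                       stages = .STAGES,
                       ploidies = .PLOIDIES,
                       baseline_log_mean = 7,
                       baseline_log_sd = 2,
                       dispersion = 0.1,
                       libsize_cv = 0.3,
                       pattern_fractions = c(additive = 0.05, hp_eld = 0.05,
                                             lp_eld = 0.05,
                                             transgressive_up = 0.05,
                                             transgressive_down = 0.05),
                       effect_log2fc = 2,
                       seed = 17L) {
  stopifnot(is.numeric(n_genes), length(n_genes) == 1L, n_genes >= 1,
            n_replicates >= 1, length(stages) >= 1, length(ploidies) >= 1)
  if (!is.numeric(dispersion) || dispersion <= 0)
    stop("'dispersion' must be strictly positive", call. = FALSE)
  if (baseline_log_sd < 0)
    stop("'baseline_log_sd' must be non-negative", call. = FALSE)
  if (libsize_cv < 0 || libsize_cv >= 1)
    stop("'libsize_cv' must be in [0, 1)", call. = FALSE)
  if (effect_log2fc < 1)
    stop("'effect_log2fc' must be >= 1", call. = FALSE)
  if (length(pattern_fractions)) {
    bad <- setdiff(names(pattern_fractions), .DOMINANCE_GROUPS)
    if (length(bad))
      stop("unknown pattern group(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    if (any(pattern_fractions < 0))
      stop("pattern fractions must be non-negative", call. = FALSE)
    if (sum(pattern_fractions) > 1)
      stop("pattern fractions sum to more than 1", call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_replicates = as.integer(n_replicates),
                 stages = stages, ploidies = ploidies,
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 dispersion = dispersion, libsize_cv = libsize_cv,
                 pattern_fractions = pattern_fractions,
                 effect_log2fc = effect_log2fc,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# run expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a hybrid/parent count experiment with planted dominance patterns
#'
#' Draws negative-binomial counts for a full ploidy x stage x role x replicate
#' design. Genes are shuffled with the seeded RNG and contiguous blocks are
#' assigned to the planted dominance groups in the fixed order `additive`,
#' `hp_eld`, `lp_eld`, `transgressive_up`, `transgressive_down` (block sizes
#' `floor(fraction * n_genes)`); remaining genes are conserved. Group means on
#' the log2 scale place every planted significant pairwise difference exactly
#' `effect_log2fc` apart:
#' \itemize{
#'   \item conserved: both parents and hybrid at the baseline;
#'   \item additive: parents at baseline +/- effect, hybrid at the geometric
#'     mid-parent (the baseline), so the hybrid is `effect_log2fc` from each
#'     parent;
#'   \item hp_eld / lp_eld: parents separated by the effect, hybrid equal to
#'     the high (resp. low) parent;
#'   \item transgressive up/down: parents equal at baseline, hybrid
#'     `effect_log2fc` above (resp. below) both.
#' }
#' The same per-gene pattern is planted in every (ploidy, stage) block. Which
#' parent is the high one is randomised per gene.
#'
#' @param config a [sim_config()] object.
#' @return list with `counts` (integer matrix, genes x samples), `design`
#'   (data.frame: sample_id, ploidy, role, stage, replicate), `truth`
#'   (data.frame: gene_id, group, true log2 means for maternal/paternal/hybrid
#'   and the library-size-free baseline), and `size_factors_true`.
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    G <- config$n_genes
    gene_ids <- sprintf("gene_%05d", seq_len(G))

    # seeded shuffle then contiguous block assignment, in canonical order
    perm <- sample.int(G)
    group <- rep("conserved", G)
    pos <- 0L
    for (g in .DOMINANCE_GROUPS) {
      f <- unname(config$pattern_fractions[g])
      if (length(f) != 1 || is.na(f)) f <- 0
      k <- floor(f * G)
      if (k > 0) {
        group[perm[(pos + 1L):(pos + k)]] <- g
        pos <- pos + k
      }
    }

    e <- config$effect_log2fc
    base <- rnorm(G, config$baseline_log_mean, config$baseline_log_sd)
    hi_is_maternal <- runif(G) < 0.5

    lm_hi <- base; lm_lo <- base; lm_f1 <- base
    i <- group == "additive"
    lm_hi[i] <- base[i] + e; lm_lo[i] <- base[i] - e
    i <- group == "hp_eld"
    lm_hi[i] <- base[i] + e; lm_f1[i] <- base[i] + e
    i <- group == "lp_eld"
    lm_hi[i] <- base[i] + e
    i <- group == "transgressive_up"
    lm_f1[i] <- base[i] + e
    i <- group == "transgressive_down"
    lm_f1[i] <- base[i] - e

    lm_mat <- ifelse(hi_is_maternal, lm_hi, lm_lo)
    lm_pat <- ifelse(hi_is_maternal, lm_lo, lm_hi)

    design <- expand.grid(replicate = seq_len(config$n_replicates),
                          role = .ROLES,
                          stage = config$stages,
                          ploidy = config$ploidies,
                          KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
    design <- design[, c("ploidy", "role", "stage", "replicate")]
    design$sample_id <- sprintf("%s_%s_%s_r%d", design$ploidy, design$role,
                                design$stage, design$replicate)
    design <- design[, c("sample_id", "ploidy", "role", "stage", "replicate")]

    n_samp <- nrow(design)
    if (config$libsize_cv > 0) {
      sdlog <- sqrt(log(1 + config$libsize_cv^2))
      sf <- exp(rnorm(n_samp, 0, sdlog))
      sf <- sf / exp(mean(log(sf)))   # geometric mean 1
    } else sf <- rep(1, n_samp)

    mu_role <- cbind(maternal = 2^lm_mat, paternal = 2^lm_pat,
                     hybrid = 2^lm_f1)
    counts <- matrix(0L, G, n_samp,
                     dimnames = list(gene_ids, design$sample_id))
    for (j in seq_len(n_samp)) {
      mu <- mu_role[, design$role[j]] * sf[j]
      counts[, j] <- rnbinom(G, mu = mu, size = 1 / config$dispersion)
    }

    truth <- data.frame(gene_id = gene_ids, group = group,
                        log2_mean_maternal = lm_mat,
                        log2_mean_paternal = lm_pat,
                        log2_mean_hybrid = lm_f1,
                        log2_baseline = base,
                        stringsAsFactors = FALSE)
    list(counts = counts, design = design, truth = truth,
         size_factors_true = setNames(sf, design$sample_id))
  })
}

#' Generate random gene intervals
#'
#' Places one interval per gene on `n_chromosomes` chromosomes of equal
#' length, 0-based half-open, entirely within chromosome bounds.
#'
#' @param n_genes number of genes.
#' @param n_chromosomes number of chromosomes (named `chr1`, `chr2`, ...).
#' @param chrom_length chromosome length in bp.
#' @param seed RNG seed.
#' @param min_len,max_len gene length range in bp.
#' @return data.frame (gene_id, chrom, start, end, strand) of class
#'   `"gene_intervals"`.
#' @export
generate_annotation <- function(n_genes, n_chromosomes = 12L,
                                chrom_length = 1e6, seed = 17L,
                                min_len = 500L, max_len = 5000L) {
  stopifnot(n_genes >= 1, n_chromosomes >= 1, min_len >= 1,
            max_len >= min_len)
  if (chrom_length <= max_len)
    stop("'chrom_length' too small to place intervals", call. = FALSE)
  with_seed(seed, {
    len <- sample(min_len:max_len, n_genes, replace = TRUE)
    chrom <- paste0("chr", sample.int(n_chromosomes, n_genes, replace = TRUE))
    start <- floor(runif(n_genes, 0, chrom_length - len))
    ann <- data.frame(gene_id = sprintf("gene_%05d", seq_len(n_genes)),
                      chrom = chrom, start = start, end = start + len,
                      strand = sample(c("+", "-"), n_genes, replace = TRUE),
                      stringsAsFactors = FALSE)
    class(ann) <- c("gene_intervals", "data.frame")
    ann
  })
}

#' Generate random QTL intervals per trait
#'
#' @param traits character vector of trait names.
#' @param per_trait QTLs per trait.
#' @param n_chromosomes,chrom_length chromosome universe.
#' @param seed RNG seed.
#' @param min_len,max_len QTL interval length range in bp.
#' @return data.frame (qtl_id, trait, chrom, start, end) of class
#'   `"qtl_intervals"`, 0-based half-open.
#' @export
generate_qtls <- function(traits, per_trait, n_chromosomes = 12L,
                          chrom_length = 1e6, seed = 17L,
                          min_len = 10000L, max_len = 50000L) {
  stopifnot(per_trait >= 1, max_len >= min_len)
  if (chrom_length <= max_len)
    stop("'chrom_length' too small to place intervals", call. = FALSE)
  if (!length(traits)) {
    q <- data.frame(qtl_id = character(), trait = character(),
                    chrom = character(), start = numeric(), end = numeric(),
                    stringsAsFactors = FALSE)
    class(q) <- c("qtl_intervals", "data.frame")
    return(q)
  }
  with_seed(seed, {
    n <- length(traits) * per_trait
    len <- sample(min_len:max_len, n, replace = TRUE)
    chrom <- paste0("chr", sample.int(n_chromosomes, n, replace = TRUE))
    start <- floor(runif(n, 0, chrom_length - len))
    q <- data.frame(qtl_id = sprintf("qtl_%04d", seq_len(n)),
                    trait = rep(traits, each = per_trait),
                    chrom = chrom, start = start, end = start + len,
                    stringsAsFactors = FALSE)
    class(q) <- c("qtl_intervals", "data.frame")
    q
  })
}

#' Simulate cytology cell counts
#'
#' Number of normal cells among `n_cells` observed, binomial at `true_rate`.
#'
#' @param true_rate probability a cell is scored normal, in `[0, 1]`.
#' @param n_cells number of cells observed.
#' @param seed RNG seed.
#' @return list(normal, total).
#' @export
generate_cytology_counts <- function(true_rate, n_cells, seed = 17L) {
  stopifnot(is.numeric(true_rate), true_rate >= 0, true_rate <= 1,
            n_cells >= 1)
  with_seed(seed, list(normal = rbinom(1L, n_cells, true_rate),
                       total = as.integer(n_cells)))
}
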