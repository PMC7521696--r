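# Differential expression core: normalization, replicate QC, per-gene
# negative-binomial Wald contrasts, BH adjustment and DEG calling.

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median ratio of each
#' sample's counts to the per-gene geometric-mean reference, over genes with
#' no zero count, then rescaled to geometric mean 1.
#'
#' @param counts integer matrix, genes x samples.
#' @return named numeric vector of positive size factors (geometric mean 1).
#' @export
size_factors <- function(counts) {
  stopifnot(is.matrix(counts), ncol(counts) >= 1)
  use <- rowSums(counts == 0) == 0
  if (!any(use))
    stop("no genes with nonzero counts in every sample; ",
         "median-of-ratios is undefined (consider a CPM-style fallback)",
         call. = FALSE)
  x <- counts[use, , drop = FALSE]
  ref <- exp(rowMeans(log(x)))
  sf <- apply(x / ref, 2, median)
  sf <- sf / exp(mean(log(sf)))
  setNames(sf, colnames(counts))
}

#' Replicate quality control by within-group correlation
#'
#' Computes Pearson correlations on log2(normalized count + 1) among the
#' replicates of each (ploidy, role, stage) group and flags a sample for
#' removal when its best within-group correlation falls below `min_corr`.
#' A group is never reduced below two retained replicates: if filtering would
#' do so, the least-bad samples are kept with a warning.
#'
#' @param counts integer matrix, genes x samples.
#' @param design design data.frame (see [read_design()]).
#' @param min_corr minimum acceptable within-group correlation (default 0.8).
#' @return character vector of retained sample ids.
#' @export
qc_replicates <- function(counts, design, min_corr = 0.8) {
  stopifnot(min_corr >= 0, min_corr <= 1)
  sf <- size_factors(counts)
  y <- log2(sweep(counts, 2, sf, "/") + 1)
  keep <- character()
  grp <- interaction(design$ploidy, design$role, design$stage, drop = TRUE)
  for (g in levels(grp)) {
    ids <- design$sample_id[grp == g]
    if (length(ids) < 2) { keep <- c(keep, ids); next }
    cm <- cor(y[, ids, drop = FALSE])
    diag(cm) <- NA
    best <- apply(cm, 2, max, na.rm = TRUE)
    ok <- best >= min_corr
    if (sum(ok) < 2) {
      warning("group ", g, ": correlation filter would leave < 2 replicates; ",
              "keeping the two best-correlated samples")
      ok[order(best, decreasing = TRUE)[1:2]] <- TRUE
    }
    if (any(!ok))
      warning("group ", g, ": dropping sample(s) ",
              paste(ids[!ok], collapse = ", "),
              " (max within-group correlation < ", min_corr, ")")
    keep <- c(keep, ids[ok])
  }
  keep
}

resolve_group <- function(design, spec) {
  if (is.character(spec) && all(spec %in% design$sample_id)) return(spec)
  if (is.list(spec)) {
    sel <- rep(TRUE, nrow(design))
    for (nm in names(spec)) {
      if (!nm %in% names(design))
        stop("unknown design column '", nm, "'", call. = FALSE)
      sel <- sel & design[[nm]] %in% spec[[nm]]
    }
    ids <- design$sample_id[sel]
    if (!length(ids)) stop("group selector matches no samples", call. = FALSE)
    return(ids)
  }
  stop("group must be sample ids or a named list of design filters",
       call. = FALSE)
}

#' Two-group negative-binomial contrast
#'
#' Per-gene NB model on median-of-ratios-normalized counts with gene-wise
#' method-of-moments dispersion (pooled within-group), shrunk 50/50 toward
#' the mean dispersion of similarly expressed genes (20 expression bins),
#' floored at 1e-4. A Wald test is applied to the log2 fold change
#' `log2((mean_a + 0.5) / (mean_b + 0.5))` with a delta-method standard
#' error. Genes with zero counts in all samples of both groups are excluded
#' from testing and reported with `tested = FALSE` (they are also excluded
#' from the BH family).
#'
#' @param counts integer matrix, genes x samples.
#' @param design design data.frame.
#' @param group_a,group_b either character vectors of sample ids or named
#'   lists of design filters, e.g. `list(ploidy = "4x", role = "hybrid",
#'   stage = "meiosis")`. Fold changes are a over b.
#' @param sf optional precomputed size factors for all samples of `counts`.
#' @return data.frame of class `"contrast_result"` with columns gene_id,
#'   mean_a, mean_b, log2fc, p_raw, q_fdr, tested.
#' @export
test_contrast <- function(counts, design, group_a, group_b, sf = NULL) {
  a <- resolve_group(design, group_a)
  b <- resolve_group(design, group_b)
  if (length(intersect(a, b))) stop("groups must be disjoint", call. = FALSE)
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs >= 2 samples", call. = FALSE)
  if (is.null(sf)) sf <- size_factors(counts)
  y <- sweep(counts, 2, sf[colnames(counts)], "/")
  ya <- y[, a, drop = FALSE]; yb <- y[, b, drop = FALSE]
  na <- length(a); nb <- length(b)

  ma <- rowMeans(ya); mb <- rowMeans(yb)
  tested <- !(rowSums(counts[, c(a, b), drop = FALSE]) == 0)

  mu <- (na * ma + nb * mb) / (na + nb)
  va <- apply(ya, 1, var); vb <- apply(yb, 1, var)
  s2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  phi <- (s2 - mu) / mu^2
  phi[!is.finite(phi)] <- 0
  phi <- pmax(phi, 0)

  # trend: mean dispersion of similarly expressed genes (20 bins by mean rank)
  idx <- which(tested)
  trend <- rep(NA_real_, length(phi))
  if (length(idx)) {
    nb_bins <- max(1L, min(20L, length(idx)))
    bins <- cut(rank(mu[idx], ties.method = "first"), breaks = nb_bins,
                labels = FALSE)
    trend[idx] <- ave(phi[idx], bins, FUN = mean)
  }
  phi_shrunk <- pmax(0.5 * phi + 0.5 * trend, 1e-4)

  log2fc <- log2((ma + 0.5) / (mb + 0.5))
  vA <- (ma + phi_shrunk * ma^2) / na
  vB <- (mb + phi_shrunk * mb^2) / nb
  se <- sqrt(vA / (ma + 0.5)^2 + vB / (mb + 0.5)^2) / log(2)
  z <- log2fc / se
  p <- 2 * pnorm(-abs(z))
  p[!tested] <- NA_real_
  q <- rep(NA_real_, length(p))
  q[tested] <- bh_adjust(p[tested])

  res <- data.frame(gene_id = rownames(counts), mean_a = ma, mean_b = mb,
                    log2fc = log2fc, p_raw = p, q_fdr = q, tested = tested,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("contrast_result", "data.frame")
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values numeric vector of p-values in `[0, 1]`; NA/NaN is an error.
#' @return q-values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric())
  if (anyNA(p_values)) stop("NA/NaN p-values not allowed", call. = FALSE)
  if (any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p_values, method = "BH")
}

#' DEG thresholds
#' @param fc_min minimum fold change (linear scale), >= 1; default 2.
#' @param fdr_max maximum FDR q-value, in (0, 1]; default 0.05.
#' @return list of class `"deg_thresholds"`.
#' @export
deg_thresholds <- function(fc_min = 2, fdr_max = 0.05) {
  stopifnot(fc_min >= 1, fdr_max > 0, fdr_max <= 1)
  structure(list(fc_min = fc_min, fdr_max = fdr_max),
            class = "deg_thresholds")
}

#' Call differentially expressed genes
#'
#' A gene is called when `|log2fc| >= log2(fc_min)` AND `q_fdr <= fdr_max`
#' (both bounds inclusive). Untested genes are never called.
#'
#' @param result a `contrast_result` from [test_contrast()].
#' @param thresholds a [deg_thresholds()] object.
#' @return data.frame (gene_id, direction, log2fc, q_fdr) of the called genes.
#' @export
call_degs <- function(result, thresholds = deg_thresholds()) {
  stopifnot(inherits(thresholds, "deg_thresholds"))
  ok <- result$tested &
    abs(result$log2fc) >= log2(thresholds$fc_min) &
    result$q_fdr <= thresholds$fdr_max
  ok[is.na(ok)] <- FALSE
  out <- result[ok, c("gene_id", "log2fc", "q_fdr")]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  rownames(out) <- NULL
  out[, c("gene_id", "direction", "log2fc", "q_fdr")]
}

#' Relative expression by the 2^-ddCt method
#'
#' Relative expression of a target gene in a sample versus a calibrator,
#' each normalized to a reference gene:
#' `2^-((ct_target_sample - ct_ref_sample) -
#'      (ct_target_calibrator - ct_ref_calibrator))`.
#'
#' @param ct_target_sample,ct_ref_sample,ct_target_calibrator,ct_ref_calibrator
#'   finite Ct values.
#' @return relative expression (1 = no change).
#' @export
relative_expression_ddct <- function(ct_target_sample, ct_ref_sample,
                                     ct_target_calibrator,
                                     ct_ref_calibrator) {
  cts <- c(ct_target_sample, ct_ref_sample, ct_target_calibrator,
           ct_ref_calibrator)
  if (!all(is.finite(cts))) stop("Ct values must be finite", call. = FALSE)
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_calibrator - ct_ref_calibrator)
  2^(-ddct)
}
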