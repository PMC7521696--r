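# Central analysis: contrasts, DEG families, ploidy-specific sets and
# dominance classification for every (ploidy, stage), bundled in one object.

#' Hybrid/parent expression-dominance analysis
#'
#' Runs the comparative analysis for every (ploidy, stage) block present in
#' the design: replicate QC, the three contrasts (parents against each other
#' and the hybrid against each parent), DEG calling under the dual
#' fold-change/FDR criterion, DEG set families, ploidy-specific hybrid-parent
#' DEG sets per stage (autotetraploid minus diploid), twelve-pattern
#' expression-dominance classification of those sets, and heterosis-candidate
#' extraction with the cross-stage intersection.
#'
#' @param counts integer matrix, genes x samples.
#' @param design design data.frame (sample_id, ploidy, role, stage,
#'   replicate).
#' @param thresholds [deg_thresholds()]; default FC >= 2, FDR <= 0.05.
#' @param min_corr replicate QC correlation threshold (default 0.8).
#' @param qc apply replicate QC before testing (default TRUE).
#' @return object of class `"polyhet"`: list with elements `contrasts`
#'   (per ploidy:stage, the three `contrast_result`s), `families`
#'   (per ploidy:stage `deg_set_family`), `specific` (per stage
#'   ploidy-specific gene sets), `dominance` (per stage `dominance_calls`),
#'   `summary` (per stage group counts/percentages), `candidates` (per stage
#'   heterosis candidates), `common_candidates`, `retained_samples`,
#'   `thresholds`, `universe` (tested genes per stage).
#' @export
polyhet <- function(counts, design, thresholds = deg_thresholds(),
                    min_corr = 0.8, qc = TRUE) {
  stopifnot(is.matrix(counts))
  if (!setequal(colnames(counts), design$sample_id))
    stop("design samples do not match count-matrix samples", call. = FALSE)

  retained <- if (qc) qc_replicates(counts, design, min_corr) else
    design$sample_id
  design <- design[design$sample_id %in% retained, , drop = FALSE]
  counts <- counts[, design$sample_id, drop = FALSE]
  sf <- size_factors(counts)

  stages <- unique(design$stage)
  ploidies <- unique(design$ploidy)

  contrasts <- list(); families <- list()
  for (pl in ploidies) for (st in stages) {
    sel <- list(ploidy = pl, stage = st)
    has <- function(role) sum(design$ploidy == pl & design$stage == st &
                                design$role == role) >= 2
    if (!has("maternal") || !has("paternal") || !has("hybrid")) next
    key <- paste(pl, st, sep = ":")
    res_pp <- test_contrast(counts, design, c(sel, role = "maternal"),
                            c(sel, role = "paternal"), sf = sf)
    res_mf <- test_contrast(counts, design, c(sel, role = "hybrid"),
                            c(sel, role = "maternal"), sf = sf)
    res_ff <- test_contrast(counts, design, c(sel, role = "hybrid"),
                            c(sel, role = "paternal"), sf = sf)
    contrasts[[key]] <- list(pp = res_pp, f1_maternal = res_mf,
                             f1_paternal = res_ff)
    families[[key]] <- build_family(call_degs(res_pp, thresholds),
                                    call_degs(res_mf, thresholds),
                                    call_degs(res_ff, thresholds),
                                    ploidy = pl, stage = st)
  }
  if (!length(families))
    stop("no (ploidy, stage) block has >= 2 replicates for all three roles",
         call. = FALSE)

  specific <- list(); dominance <- list(); summaries <- list()
  candidates <- list(); universe <- list()
  for (st in stages) {
    k4 <- paste("4x", st, sep = ":"); k2 <- paste("2x", st, sep = ":")
    target_key <- if (!is.null(families[[k4]])) k4 else
      grep(paste0(":", st, "$"), names(families), value = TRUE)[1]
    if (is.na(target_key) || is.null(families[[target_key]])) next
    genes <- if (!is.null(families[[k4]]) && !is.null(families[[k2]]))
      ploidy_specific(families[[k4]], families[[k2]])
    else families[[target_key]]$degs_hp
    specific[[st]] <- genes
    cs <- contrasts[[target_key]]
    # classify on the hybrid-vs-parent and parent-parent contrasts; parent 1
    # is the maternal line (pp has maternal as group a)
    dom <- classify_all(genes, cs$f1_maternal, cs$f1_paternal, cs$pp,
                        thresholds)
    dominance[[st]] <- dom
    summaries[[st]] <- summarize_dominance(dom)
    candidates[[st]] <- heterosis_candidates(dom)
    universe[[st]] <- cs$pp$gene_id[cs$pp$tested]
  }
  common <- if (length(candidates) >= 2)
    Reduce(cross_stage_common, candidates) else character()

  structure(list(contrasts = contrasts, families = families,
                 specific = specific, dominance = dominance,
                 summary = summaries, candidates = candidates,
                 common_candidates = common, retained_samples = retained,
                 thresholds = thresholds, universe = universe),
            class = "polyhet")
}

#' @export
print.polyhet <- function(x, ...) {
  cat("polyhet analysis\n")
  cat("  thresholds: FC >=", x$thresholds$fc_min,
      ", FDR <=", x$thresholds$fdr_max, "\n")
  cat("  retained samples:", length(x$retained_samples), "\n")
  for (key in names(x$families)) {
    f <- x$families[[key]]
    cat(sprintf("  %-22s DEGs_PP %5d | M/F1 %5d | F/F1 %5d | DEGs_HP %5d\n",
                key, length(f$degs_pp), length(f$degs_mf1),
                length(f$degs_ff1), length(f$degs_hp)))
  }
  for (st in names(x$specific))
    cat(sprintf("  %-22s ploidy-specific DEGs_HP %5d, candidates %d\n",
                st, length(x$specific[[st]]), length(x$candidates[[st]])))
  if (length(x$common_candidates))
    cat("  candidates common to stages:", length(x$common_candidates), "\n")
  invisible(x)
}

#' @export
summary.polyhet <- function(object, ...) {
  out <- list()
  for (st in names(object$summary)) {
    s <- object$summary[[st]]
    s$stage <- st
    out[[st]] <- s
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("stage", "group", "count", "percent")]
}

#' Barplot of dominance-group percentages per stage
#' @param x a `polyhet` object.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.polyhet <- function(x, ...) {
  s <- summary(x)
  m <- tapply(s$percent, list(s$group, s$stage), identity)
  m <- m[.DOMINANCE_GROUPS, , drop = FALSE]
  graphics::barplot(m, beside = TRUE, legend.text = rownames(m),
                    ylab = "% of classified DEGs_HP",
                    args.legend = list(x = "topleft", bty = "n"), ...)
  invisible(x)
}
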