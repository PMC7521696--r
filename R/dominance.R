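# Twelve-pattern expression-dominance classification of hybrid-parent DEGs,
# five-group aggregation, and heterosis-candidate extraction.
#
# Each gene carries three significance calls (hybrid vs parent 1, hybrid vs
# parent 2, parent 1 vs parent 2), each in {+, -, 0} under the dual
# fold-change/FDR criterion, plus the parents' normalized means to decide
# which parent is the high (H) and which the low (L) one. The twelve patterns
# follow the standard additive/ELD/transgressive scheme:
#   2 additive        : parents differ, hybrid significantly between them
#   2 high-parent ELD : parents differ, hybrid = H, hybrid above L
#   2 low-parent ELD  : parents differ, hybrid = L, hybrid below H
#   3 transgressive up: hybrid significantly above BOTH parents
#   3 transgressive dn: hybrid significantly below BOTH parents
# (the additive/ELD pairs split by which parent is higher; the transgressive
# triples split by the parent-parent call). Everything else, including the
# all-nonsignificant configuration, is unclassified.

.PATTERNS <- data.frame(
  pattern = c("I", "II", "III", "IV", "V", "VI",
              "VII", "VIII", "IX", "X", "XI", "XII"),
  group = c("additive", "additive", "hp_eld", "hp_eld", "lp_eld", "lp_eld",
            "transgressive_up", "transgressive_up", "transgressive_up",
            "transgressive_down", "transgressive_down", "transgressive_down"),
  stringsAsFactors = FALSE
)

#' Classify one gene's expression-dominance pattern
#'
#' @param call_f1_p1 significance call for hybrid vs parent 1: `"+"` (hybrid
#'   significantly higher), `"-"` (lower) or `"0"` (not significant) under
#'   the dual FC/FDR criterion.
#' @param call_f1_p2 same for hybrid vs parent 2.
#' @param call_p1_p2 same for parent 1 vs parent 2.
#' @param mean_p1,mean_p2 normalized parent means, used to orient the
#'   high/low parent; only needed when the parents differ significantly.
#' @return list(pattern, group); `pattern` is `"I"`..`"XII"` or NA and
#'   `group` one of additive, hp_eld, lp_eld, transgressive_up,
#'   transgressive_down, unclassified.
#' @export
classify_gene <- function(call_f1_p1, call_f1_p2, call_p1_p2,
                          mean_p1 = NA_real_, mean_p2 = NA_real_) {
  ok <- c("+", "-", "0")
  if (!(call_f1_p1 %in% ok && call_f1_p2 %in% ok && call_p1_p2 %in% ok))
    stop("calls must be one of '+', '-', '0'", call. = FALSE)

  unclass_ <- list(pattern = NA_character_, group = "unclassified")

  # transgressive: hybrid beyond both parents, any parental relation
  if (call_f1_p1 == "+" && call_f1_p2 == "+") {
    pat <- switch(call_p1_p2, "+" = "VII", "0" = "VIII", "-" = "IX")
    return(list(pattern = pat, group = "transgressive_up"))
  }
  if (call_f1_p1 == "-" && call_f1_p2 == "-") {
    pat <- switch(call_p1_p2, "+" = "X", "0" = "XI", "-" = "XII")
    return(list(pattern = pat, group = "transgressive_down"))
  }

  # remaining patterns require significantly different parents
  if (call_p1_p2 == "0") return(unclass_)
  p1_high <- call_p1_p2 == "+"
  # guard: the parent call must agree with the means when both are given
  if (is.finite(mean_p1) && is.finite(mean_p2) &&
      (mean_p1 > mean_p2) != p1_high && mean_p1 != mean_p2)
    stop("parent-parent call contradicts parent means", call. = FALSE)
  call_f1_h <- if (p1_high) call_f1_p1 else call_f1_p2
  call_f1_l <- if (p1_high) call_f1_p2 else call_f1_p1

  # additive: hybrid significantly differs from both parents in opposite
  # directions while the parents differ -- intermediate expression
  if ((call_f1_p1 == "-" && call_f1_p2 == "+") ||
      (call_f1_p1 == "+" && call_f1_p2 == "-"))
    list(pattern = if (p1_high) "I" else "II", group = "additive")
  else if (call_f1_h == "0" && call_f1_l == "+")  # matches the high parent
    list(pattern = if (p1_high) "III" else "IV", group = "hp_eld")
  else if (call_f1_h == "-" && call_f1_l == "0")  # matches the low parent
    list(pattern = if (p1_high) "V" else "VI", group = "lp_eld")
  else unclass_
}

sig_call <- function(result, thresholds) {
  lfc_min <- log2(thresholds$fc_min)
  sig <- result$tested & !is.na(result$q_fdr) &
    abs(result$log2fc) >= lfc_min & result$q_fdr <= thresholds$fdr_max
  out <- rep("0", nrow(result))
  out[sig & result$log2fc > 0] <- "+"
  out[sig & result$log2fc < 0] <- "-"
  setNames(out, result$gene_id)
}

#' Classify all hybrid-parent DEGs
#'
#' Derives the three significance calls per gene from the contrast results
#' (hybrid vs parent 1, hybrid vs parent 2, parent 1 vs parent 2; each with
#' the hybrid/parent-1 as group a) and classifies every gene of `deg_hp_genes`.
#'
#' @param deg_hp_genes character vector of genes to classify (typically a
#'   `degs_hp` set or its ploidy-specific subset).
#' @param res_f1_p1,res_f1_p2 `contrast_result`s for hybrid vs each parent
#'   (hybrid is group a).
#' @param res_p1_p2 `contrast_result` for parent 1 vs parent 2 (parent 1 is
#'   group a).
#' @param thresholds a [deg_thresholds()] object; the same dual criterion
#'   used for DEG calling defines the per-contrast significance calls.
#' @return data.frame (gene_id, pattern, group) of class `"dominance_calls"`.
#' @export
classify_all <- function(deg_hp_genes, res_f1_p1, res_f1_p2, res_p1_p2,
                         thresholds = deg_thresholds()) {
  deg_hp_genes <- unique(as.character(deg_hp_genes))
  for (res in list(res_f1_p1, res_f1_p2, res_p1_p2)) {
    miss <- setdiff(deg_hp_genes, res$gene_id)
    if (length(miss))
      stop("contrast results missing ", length(miss), " gene(s), e.g. ",
           miss[1], call. = FALSE)
  }
  c1 <- sig_call(res_f1_p1, thresholds)
  c2 <- sig_call(res_f1_p2, thresholds)
  c3 <- sig_call(res_p1_p2, thresholds)
  # parent means: parent 1 is group b of res_f1_p1; also group a of res_p1_p2
  m1 <- setNames(res_p1_p2$mean_a, res_p1_p2$gene_id)
  m2 <- setNames(res_p1_p2$mean_b, res_p1_p2$gene_id)
  out <- lapply(deg_hp_genes, function(g)
    classify_gene(c1[[g]], c2[[g]], c3[[g]], m1[[g]], m2[[g]]))
  calls <- data.frame(gene_id = deg_hp_genes,
                      pattern = vapply(out, `[[`, "", "pattern"),
                      group = vapply(out, `[[`, "", "group"),
                      stringsAsFactors = FALSE)
  class(calls) <- c("dominance_calls", "data.frame")
  calls
}

#' Summarize dominance calls into group counts and percentages
#'
#' Percentages are of classified genes (unclassified genes are reported as a
#' separate count but excluded from the denominator), rounded to 2 decimals.
#'
#' @param calls `dominance_calls` data.frame (or any data.frame with a
#'   `group` column).
#' @return data.frame (group, count, percent) over the five dominance groups,
#'   with attributes `n_classified` and `n_unclassified`.
#' @export
summarize_dominance <- function(calls) {
  if (!nrow(calls))
    return(structure(data.frame(group = character(), count = integer(),
                                percent = numeric(),
                                stringsAsFactors = FALSE),
                     n_classified = 0L, n_unclassified = 0L))
  grp <- factor(calls$group, levels = c(.DOMINANCE_GROUPS, "unclassified"))
  cnt <- table(grp)
  n_uncl <- as.integer(cnt[["unclassified"]])
  cnt <- cnt[.DOMINANCE_GROUPS]
  total <- sum(cnt)
  pct <- if (total > 0) round(100 * as.integer(cnt) / total, 2) else
    rep(NA_real_, length(cnt))
  structure(data.frame(group = .DOMINANCE_GROUPS, count = as.integer(cnt),
                       percent = pct, row.names = NULL,
                       stringsAsFactors = FALSE),
            n_classified = as.integer(total), n_unclassified = n_uncl)
}

#' Extract heterosis candidate genes
#'
#' Candidates are the genes classified as high-parent expression-level
#' dominance or transgressive up-regulation.
#'
#' @param calls `dominance_calls` data.frame.
#' @return character vector of gene ids.
#' @export
heterosis_candidates <- function(calls) {
  unique(calls$gene_id[calls$group %in% c("hp_eld", "transgressive_up")])
}

#' Candidate genes common to two stages
#' @param candidates_stage1,candidates_stage2 character vectors of gene ids.
#' @return their intersection.
#' @export
cross_stage_common <- function(candidates_stage1, candidates_stage2) {
  intersect(unique(as.character(candidates_stage1)),
            unique(as.character(candidates_stage2)))
}
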