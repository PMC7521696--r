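# DEG set algebra: parent-parent / hybrid-parent families, ploidy-specific
# sets and Venn region counts. Direction is ignored: sets contain gene ids.

#' Build a DEG set family for one (ploidy, stage)
#'
#' Combines the parent-vs-parent call set and the two hybrid-vs-parent call
#' sets; the hybrid-parent family `degs_hp` is their union.
#'
#' @param calls_pp,calls_mf1,calls_ff1 DEG calls (data.frames from
#'   [call_degs()] or character vectors of gene ids) for the parent-parent,
#'   maternal-vs-F1 and paternal-vs-F1 contrasts of a single (ploidy, stage).
#' @param ploidy,stage labels attached to the family; [ploidy_specific()]
#'   and downstream steps check them.
#' @return list of class `"deg_set_family"`: degs_pp, degs_mf1, degs_ff1,
#'   degs_hp (character vectors) plus ploidy and stage.
#' @export
build_family <- function(calls_pp, calls_mf1, calls_ff1,
                         ploidy = NA_character_, stage = NA_character_) {
  as_set <- function(x) {
    if (is.data.frame(x)) x <- x$gene_id
    unique(as.character(x))
  }
  pp <- as_set(calls_pp); mf1 <- as_set(calls_mf1); ff1 <- as_set(calls_ff1)
  fam <- list(degs_pp = pp, degs_mf1 = mf1, degs_ff1 = ff1,
              degs_hp = union(mf1, ff1), ploidy = ploidy, stage = stage)
  class(fam) <- "deg_set_family"
  fam
}

#' Ploidy-specific hybrid-parent DEGs
#'
#' Genes in the autotetraploid family's `degs_hp` that are absent from the
#' diploid family's `degs_hp` at the same stage.
#'
#' @param family_4x,family_2x `deg_set_family` objects, or plain character
#'   vectors of gene ids.
#' @return character vector of ploidy-specific gene ids.
#' @export
ploidy_specific <- function(family_4x, family_2x) {
  get_hp <- function(x) if (inherits(x, "deg_set_family")) x$degs_hp
    else unique(as.character(x))
  if (inherits(family_4x, "deg_set_family") &&
      inherits(family_2x, "deg_set_family") &&
      !is.na(family_4x$stage) && !is.na(family_2x$stage) &&
      family_4x$stage != family_2x$stage)
    stop("families come from different stages", call. = FALSE)
  setdiff(get_hp(family_4x), get_hp(family_2x))
}

#' Venn region counts for 2-4 named gene sets
#'
#' @param sets named list of 2 to 4 character vectors.
#' @return data.frame (region, count); regions are named by the sets they
#'   include, e.g. `"A&B"`; counts over all regions sum to the union size.
#' @export
venn_counts <- function(sets) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("'sets' must be a named list", call. = FALSE)
  k <- length(sets)
  if (k < 2 || k > 4)
    stop("venn_counts supports 2 to 4 sets", call. = FALSE)
  sets <- lapply(sets, function(x) unique(as.character(x)))
  all_genes <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_genes %in% s,
                   logical(length(all_genes)))
  if (length(all_genes) == 1L) member <- matrix(member, nrow = 1)
  code <- apply(member, 1, function(m) paste(names(sets)[m], collapse = "&"))
  # enumerate every non-empty region, including empty-count ones
  combos <- unlist(lapply(seq_len(k), function(m)
    utils::combn(names(sets), m, paste, collapse = "&", simplify = FALSE)))
  cnt <- table(factor(code, levels = combos))
  data.frame(region = names(cnt), count = as.integer(cnt),
             row.names = NULL, stringsAsFactors = FALSE)
}
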