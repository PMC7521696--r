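# Hypergeometric over-representation analysis with BH correction within
# annotation namespaces.

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for X ~ Hypergeometric(N, K, n): the chance of at least `k`
#' annotated genes in a draw of `n` from a universe of `N` containing `K`
#' annotated genes.
#'
#' @param k observed annotated genes in the set.
#' @param K annotated genes in the universe.
#' @param n gene-set size.
#' @param N universe size.
#' @return upper-tail probability in (0, 1].
#' @export
hypergeom_upper <- function(k, K, n, N) {
  if (any(K > N | n > N | k > pmin(K, n) | k < 0 | K < 0 | n < 0))
    stop("inconsistent hypergeometric margins", call. = FALSE)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis of a gene set
#'
#' Tests each annotation term for over-representation in `gene_set` relative
#' to `universe` with the hypergeometric upper tail; BH correction is applied
#' separately within each annotation namespace. Terms with fewer than
#' `min_term_size` universe genes are skipped.
#'
#' @param gene_set character vector of gene ids (must be within `universe`).
#' @param annotation a `term_annotation` (see [read_term_annotation()]) or a
#'   named list of term_id -> gene id vectors.
#' @param universe character vector of gene ids defining the background
#'   (typically the genes tested in the relevant contrasts).
#' @param min_term_size minimum annotated universe genes per tested term.
#' @return data.frame (term_id, namespace, k, K, n, N, p_raw, q_fdr) sorted
#'   by p_raw.
#' @export
enrich <- function(gene_set, annotation, universe, min_term_size = 3L) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe", call. = FALSE)
  gene_set <- unique(as.character(gene_set))
  out_of <- setdiff(gene_set, universe)
  if (length(out_of))
    stop(length(out_of), " gene-set gene(s) not in the universe",
         call. = FALSE)
  if (inherits(annotation, "term_annotation")) {
    terms <- annotation$terms; ns <- annotation$namespace
  } else {
    terms <- annotation
    ns <- setNames(rep("default", length(terms)), names(terms))
  }
  terms <- lapply(terms, function(g) intersect(unique(g), universe))
  keep <- lengths(terms) >= min_term_size
  terms <- terms[keep]; ns <- ns[names(terms)]
  N <- length(universe); n <- length(gene_set)
  if (!length(terms))
    return(data.frame(term_id = character(), namespace = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p_raw = numeric(), q_fdr = numeric(),
                      stringsAsFactors = FALSE))
  K <- lengths(terms)
  k <- vapply(terms, function(g) length(intersect(g, gene_set)), 1L)
  p <- hypergeom_upper(k, K, n, N)
  q <- rep(NA_real_, length(p))
  for (s in unique(ns)) {
    i <- ns == s
    q[i] <- bh_adjust(p[i])
  }
  res <- data.frame(term_id = names(terms), namespace = unname(ns),
                    k = as.integer(k), K = as.integer(K), n = n, N = N,
                    p_raw = unname(p), q_fdr = q, row.names = NULL,
                    stringsAsFactors = FALSE)
  res[order(res$p_raw, res$term_id), , drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}
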