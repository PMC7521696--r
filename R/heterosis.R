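# Heterosis indices on trait means and cytology proportion statistics.

#' Mid-parent heterosis (percent)
#'
#' `MPH = 100 * (F1 - MP) / MP` with `MP = (P1 + P2) / 2`.
#'
#' @param f1 hybrid trait mean.
#' @param p1,p2 parent trait means.
#' @param digits decimals for the reported value (default 2); use `NULL` for
#'   full precision.
#' @return MPH in percent.
#' @export
mph <- function(f1, p1, p2, digits = 2) {
  mp <- (p1 + p2) / 2
  if (any(mp == 0)) stop("mid-parent mean is zero; MPH undefined",
                         call. = FALSE)
  out <- 100 * (f1 - mp) / mp
  if (is.null(digits)) out else round(out, digits)
}

#' High-parent heterosis (percent)
#'
#' `HPH = 100 * (F1 - HP) / HP` with `HP = max(P1, P2)` (the best parent).
#'
#' @inheritParams mph
#' @return HPH in percent.
#' @export
hph <- function(f1, p1, p2, digits = 2) {
  hp <- pmax(p1, p2)
  if (any(hp == 0)) stop("best-parent mean is zero; HPH undefined",
                         call. = FALSE)
  out <- 100 * (f1 - hp) / hp
  if (is.null(digits)) out else round(out, digits)
}

#' Heterosis indices for a table of trait records
#'
#' @param records data.frame with columns trait, f1, p1, p2 (see
#'   [read_trait_table()]).
#' @param digits reporting decimals (default 2).
#' @return data.frame (trait, f1, mp, hp, mph_percent, hph_percent).
#' @export
trait_heterosis_table <- function(records, digits = 2) {
  if (!nrow(records))
    return(data.frame(trait = character(), f1 = numeric(), mp = numeric(),
                      hp = numeric(), mph_percent = numeric(),
                      hph_percent = numeric(), stringsAsFactors = FALSE))
  data.frame(trait = records$trait, f1 = records$f1,
             mp = (records$p1 + records$p2) / 2,
             hp = pmax(records$p1, records$p2),
             mph_percent = mph(records$f1, records$p1, records$p2, digits),
             hph_percent = hph(records$f1, records$p1, records$p2, digits),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pollen fertility percentage
#' @param fertile number of fertile (round, fully stained) pollen grains.
#' @param total total grains scored; must be positive.
#' @return percentage of fertile grains.
#' @export
pollen_fertility <- function(fertile, total) {
  if (any(total <= 0)) stop("total must be positive", call. = FALSE)
  if (any(fertile < 0 | fertile > total))
    stop("fertile must lie in [0, total]", call. = FALSE)
  100 * fertile / total
}

#' Frequency of normal cells per stage and pooled
#'
#' The pooled frequency uses summed counts across stages, not the mean of the
#' per-stage percentages.
#'
#' @param summaries data.frame with columns stage, normal, total.
#' @return list: `per_stage` (named numeric vector of percentages) and
#'   `overall` (pooled percentage).
#' @export
normal_cell_frequency <- function(summaries) {
  stopifnot(all(c("stage", "normal", "total") %in% names(summaries)))
  if (any(summaries$total <= 0))
    stop("zero total cell count at some stage", call. = FALSE)
  if (any(summaries$normal < 0 | summaries$normal > summaries$total))
    stop("normal count out of range", call. = FALSE)
  per <- setNames(100 * summaries$normal / summaries$total, summaries$stage)
  list(per_stage = per,
       overall = 100 * sum(summaries$normal) / sum(summaries$total))
}

#' Compare two proportions
#'
#' Chi-square test with continuity correction by default; `exact = TRUE`
#' switches to Fisher's exact test for small counts. Degenerate margins (all
#' successes or all failures pooled) return p = 1 with a warning.
#'
#' @param x1,n1 successes and trials in group 1.
#' @param x2,n2 successes and trials in group 2.
#' @param exact use Fisher's exact test.
#' @return list: `difference` (percentage points, group 1 minus group 2) and
#'   `p_value`.
#' @export
compare_proportions <- function(x1, n1, x2, n2, exact = FALSE) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  diff <- 100 * (x1 / n1 - x2 / n2)
  s <- x1 + x2; f <- (n1 - x1) + (n2 - x2)
  if (s == 0 || f == 0) {
    warning("degenerate margins: all successes or all failures")
    return(list(difference = diff, p_value = 1))
  }
  p <- if (exact)
    fisher.test(matrix(c(x1, n1 - x1, x2, n2 - x2), 2, byrow = TRUE))$p.value
  else
    prop.test(c(x1, x2), c(n1, n2), correct = TRUE)$p.value
  list(difference = diff, p_value = p)
}
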