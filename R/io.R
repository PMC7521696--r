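# Readers and writers for every external format the pipeline touches.
# Internal coordinates are 0-based half-open everywhere; conversions happen
# only at these boundaries (GFF3 and QTL TSV are 1-based inclusive on disk).

out_header <- function(params = NULL) {
  v <- tryCatch(as.character(packageVersion("polyhet")),
                error = function(e) "dev")
  p <- if (length(params))
    paste0(" ", paste(names(params), unlist(params), sep = "=",
                      collapse = " ")) else ""
  sprintf("# polyhet %s%s", v, p)
}

write_tsv_commented <- function(df, path, params = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(out_header(params), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-by-sample count matrix from TSV
#'
#' Expects a header row of sample ids; the first column holds gene ids.
#' Comment lines starting with `#` are skipped. Counts must be non-negative
#' integers and gene ids unique.
#'
#' @param path TSV file path.
#' @return integer matrix, genes x samples, with dimnames.
#' @export
read_count_matrix <- function(path) {
  df <- read.delim(path, header = TRUE, comment.char = "#",
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("count matrix needs gene_id plus >= 1 sample",
                         call. = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate gene ids in count matrix", call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric counts", call. = FALSE)
  if (anyNA(m)) stop("missing values in counts", call. = FALSE)
  if (any(m < 0)) stop("negative counts are not allowed", call. = FALSE)
  if (any(m != round(m))) stop("counts must be integers", call. = FALSE)
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample ids in count matrix", call. = FALSE)
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

#' Write a count matrix to TSV
#' @param counts integer matrix with dimnames.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_count_matrix <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_commented(df, path)
}

#' Read a sample-design table from TSV
#'
#' Required columns: sample_id, ploidy (2x/4x), role
#' (maternal/paternal/hybrid), stage, replicate.
#'
#' @param path TSV file path.
#' @param counts optional count matrix to validate sample coverage against.
#' @return data.frame.
#' @export
read_design <- function(path, counts = NULL) {
  df <- read.delim(path, header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE)
  need <- c("sample_id", "ploidy", "role", "stage", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("design table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in design", call. = FALSE)
  bad <- setdiff(df$role, .ROLES)
  if (length(bad))
    stop("unknown role(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(counts)) {
    if (!setequal(colnames(counts), df$sample_id))
      stop("design samples do not match count-matrix samples", call. = FALSE)
  }
  df
}

#' Write a design table to TSV
#' @param design data.frame as returned by [generate_experiment()].
#' @param path output path.
#' @export
write_design <- function(design, path) write_tsv_commented(design, path)

#' Read gene intervals from GFF3 or BED
#'
#' GFF3 coordinates (1-based inclusive) are converted to the internal 0-based
#' half-open convention (`start' = start - 1`, `end' = end`); BED is already
#' 0-based half-open and passes through. Gene ids come from the GFF3 `ID=`
#' attribute or BED column 4.
#'
#' @param path file path.
#' @param format `"gff3"` or `"bed"`.
#' @return data.frame (gene_id, chrom, start, end, strand) of class
#'   `"gene_intervals"`.
#' @export
read_gene_annotation <- function(path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  gr <- tryCatch(rtracklayer::import(path, format = format),
                 error = function(e)
                   stop("failed to parse ", format, " file: ",
                        conditionMessage(e), call. = FALSE))
  if (!length(gr)) {
    ann <- data.frame(gene_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      strand = character(), stringsAsFactors = FALSE)
    class(ann) <- c("gene_intervals", "data.frame")
    return(ann)
  }
  id <- if (format == "gff3") as.character(gr$ID) else as.character(gr$name)
  if (is.null(id) || anyNA(id))
    stop("every record needs an id (GFF3 ID attribute / BED name column)",
         call. = FALSE)
  # GRanges are 1-based inclusive; internal convention is 0-based half-open
  ann <- data.frame(gene_id = id,
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1,
                    end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)),
                    stringsAsFactors = FALSE)
  if (any(ann$start >= ann$end))
    stop("invalid interval: start must be < end after conversion",
         call. = FALSE)
  class(ann) <- c("gene_intervals", "data.frame")
  ann
}

#' Write gene intervals as GFF3 or BED
#'
#' Internal 0-based half-open intervals are converted back to 1-based
#' inclusive for GFF3.
#'
#' @param ann `gene_intervals` data.frame.
#' @param path output path.
#' @param format `"gff3"` or `"bed"`.
#' @export
write_gene_annotation <- function(ann, path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (format == "gff3") {
    writeLines("##gff-version 3", con)
    lines <- sprintf("%s\tpolyhet\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     ann$chrom, as.integer(ann$start) + 1L,
                     as.integer(ann$end), ann$strand, ann$gene_id)
  } else {
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", ann$chrom,
                     as.integer(ann$start), as.integer(ann$end),
                     ann$gene_id, ann$strand)
  }
  writeLines(lines, con)
  invisible(path)
}

#' Read a QTL interval table
#'
#' TSV with mandatory columns trait, chrom, start_1based, end_1based, qtl_id;
#' unknown columns are ignored with a warning. Coordinates are converted to
#' the internal 0-based half-open convention.
#'
#' @param path TSV file path.
#' @return data.frame (qtl_id, trait, chrom, start, end) of class
#'   `"qtl_intervals"`.
#' @export
read_qtl_table <- function(path) {
  df <- read.delim(path, header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE)
  need <- c("trait", "chrom", "start_1based", "end_1based", "qtl_id")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("QTL table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(names(df), need)
  if (length(extra))
    warning("ignoring unknown QTL column(s): ", paste(extra, collapse = ", "))
  q <- data.frame(qtl_id = as.character(df$qtl_id),
                  trait = as.character(df$trait),
                  chrom = as.character(df$chrom),
                  start = as.numeric(df$start_1based) - 1,
                  end = as.numeric(df$end_1based),
                  stringsAsFactors = FALSE)
  if (any(q$start >= q$end))
    stop("invalid QTL interval: start must be < end", call. = FALSE)
  class(q) <- c("qtl_intervals", "data.frame")
  q
}

#' Write a QTL table (1-based inclusive on disk)
#' @param qtls `qtl_intervals` data.frame.
#' @param path output path.
#' @export
write_qtl_table <- function(qtls, path) {
  df <- data.frame(trait = qtls$trait, chrom = qtls$chrom,
                   start_1based = as.integer(qtls$start) + 1L,
                   end_1based = as.integer(qtls$end),
                   qtl_id = qtls$qtl_id, stringsAsFactors = FALSE)
  write_tsv_commented(df, path)
}

#' Read a trait-mean table (CSV)
#'
#' Mandatory columns: trait, f1, p1, p2; optional sd and n columns are kept.
#'
#' @param path CSV file path.
#' @return data.frame of trait records.
#' @export
read_trait_table <- function(path) {
  df <- utils::read.csv(path, header = TRUE, comment.char = "#",
                        stringsAsFactors = FALSE)
  need <- c("trait", "f1", "p1", "p2")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trait table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(is.finite(df$f1)) || !all(is.finite(df$p1)) ||
      !all(is.finite(df$p2)))
    stop("trait means must be finite", call. = FALSE)
  df
}

#' Read a term-to-gene annotation table
#'
#' Two mandatory TSV columns term_id and gene_id; optional `namespace` column
#' (defaults to a single namespace `"default"`).
#'
#' @param path TSV file path.
#' @return list of class `"term_annotation"`: `terms` (named list term_id ->
#'   character vector of gene ids) and `namespace` (named character vector,
#'   one per term).
#' @export
read_term_annotation <- function(path) {
  df <- read.delim(path, header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE)
  if (!nrow(df)) {
    warning("empty term annotation")
    return(structure(list(terms = list(),
                          namespace = character()),
                     class = "term_annotation"))
  }
  need <- c("term_id", "gene_id")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("term annotation missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ns <- if ("namespace" %in% names(df)) df$namespace else
    rep("default", nrow(df))
  terms <- split(as.character(df$gene_id), df$term_id)
  terms <- lapply(terms, unique)
  ns_by_term <- vapply(split(ns, df$term_id), function(x) x[[1]], "")
  structure(list(terms = terms, namespace = ns_by_term[names(terms)]),
            class = "term_annotation")
}
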