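# End-to-end pipeline: read inputs per a config, run the analysis, write
# stage outputs and a manifest.

#' Pipeline configuration
#'
#' Builds and validates the configuration for [run_pipeline()]. Either pass
#' the fields directly or a path to a YAML file holding them.
#'
#' @param counts,design paths to the count-matrix and design TSVs (required).
#' @param annotation path to gene coordinates (GFF3 or BED), optional.
#' @param annotation_format `"gff3"` or `"bed"`.
#' @param qtls path to the QTL TSV, optional (requires `annotation`).
#' @param traits path to the trait-mean CSV, optional.
#' @param cytology path to a cytology TSV (genotype, stage, normal, total),
#'   optional.
#' @param terms path to a term-annotation TSV, optional.
#' @param fc_min,fdr_max DEG thresholds.
#' @param min_corr replicate-QC correlation threshold.
#' @param seed integer seed recorded in the manifest (the analysis itself is
#'   deterministic).
#' @param outdir output directory.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(counts, design, annotation = NULL,
                            annotation_format = "gff3", qtls = NULL,
                            traits = NULL, cytology = NULL, terms = NULL,
                            fc_min = 2, fdr_max = 0.05, min_corr = 0.8,
                            seed = 17L, outdir = "polyhet_out") {
  cfg <- list(counts = counts, design = design, annotation = annotation,
              annotation_format = annotation_format, qtls = qtls,
              traits = traits, cytology = cytology, terms = terms,
              fc_min = fc_min, fdr_max = fdr_max, min_corr = min_corr,
              seed = as.integer(seed), outdir = outdir)
  for (f in c("counts", "design")) {
    if (is.null(cfg[[f]]) || !file.exists(cfg[[f]]))
      stop("required input '", f, "' missing or file not found",
           call. = FALSE)
  }
  for (f in c("annotation", "qtls", "traits", "cytology", "terms")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("input '", f, "' file not found: ", cfg[[f]], call. = FALSE)
  }
  if (!is.null(cfg$qtls) && is.null(cfg$annotation))
    stop("QTL mapping needs 'annotation'", call. = FALSE)
  stopifnot(cfg$fc_min >= 1, cfg$fdr_max > 0, cfg$fdr_max <= 1,
            cfg$min_corr >= 0, cfg$min_corr <= 1)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; keys as in [pipeline_config()].
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the full pipeline
#'
#' Reads every configured input, runs [polyhet()], then the optional stages
#' (heterosis table, cytology frequencies, gene-to-QTL mapping of the
#' meiosis-stage ploidy-specific DEGs_HP, term enrichment of each stage's
#' ploidy-specific set against the tested-gene universe), writes all stage
#' outputs as commented TSVs under `config$outdir`, and writes a
#' `manifest.json` with inputs, parameters, seed and per-stage record counts.
#' Rerunning with the same config reproduces identical outputs.
#'
#' @param config a [pipeline_config()] (or path to its YAML file).
#' @return the manifest list, invisibly; side effect: files under
#'   `config$outdir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  params <- list(fc_min = config$fc_min, fdr_max = config$fdr_max,
                 min_corr = config$min_corr, seed = config$seed)
  manifest <- list(inputs = config[c("counts", "design", "annotation",
                                     "qtls", "traits", "cytology", "terms")],
                   parameters = params,
                   version = as.character(packageVersion("polyhet")),
                   seed = config$seed, stages = list())
  counts <- read_count_matrix(config$counts)
  design <- read_design(config$design, counts)
  thr <- deg_thresholds(config$fc_min, config$fdr_max)

  fit <- polyhet(counts, design, thr, min_corr = config$min_corr)

  outp <- function(name) file.path(config$outdir, name)
  for (key in names(fit$contrasts)) {
    safe <- gsub(":", "_", key)
    for (cn in names(fit$contrasts[[key]])) {
      res <- fit$contrasts[[key]][[cn]]
      deg <- call_degs(res, thr)
      res$called <- res$gene_id %in% deg$gene_id
      f <- outp(sprintf("contrast_%s_%s.tsv", safe, cn))
      write_tsv_commented(res, f, params)
      manifest$stages[[paste0("contrast_", safe, "_", cn)]] <- nrow(res)
    }
    fam <- fit$families[[key]]
    memb <- data.frame(gene_id = sort(Reduce(union,
                                             fam[c("degs_pp", "degs_mf1",
                                                   "degs_ff1")])),
                       stringsAsFactors = FALSE)
    for (s in c("degs_pp", "degs_mf1", "degs_ff1", "degs_hp"))
      memb[[s]] <- memb$gene_id %in% fam[[s]]
    write_tsv_commented(memb, outp(sprintf("deg_sets_%s.tsv", safe)), params)
    manifest$stages[[paste0("deg_sets_", safe)]] <- nrow(memb)
  }
  for (st in names(fit$dominance)) {
    write_tsv_commented(fit$dominance[[st]],
                        outp(sprintf("dominance_%s.tsv", st)), params)
    write_tsv_commented(fit$summary[[st]],
                        outp(sprintf("dominance_summary_%s.tsv", st)), params)
    write_tsv_commented(data.frame(gene_id = sort(fit$candidates[[st]])),
                        outp(sprintf("candidates_%s.tsv", st)), params)
    manifest$stages[[paste0("dominance_", st)]] <- nrow(fit$dominance[[st]])
    manifest$stages[[paste0("candidates_", st)]] <-
      length(fit$candidates[[st]])
  }
  write_tsv_commented(
    data.frame(gene_id = sort(fit$common_candidates)),
    outp("candidates_common.tsv"), params)
  manifest$stages$candidates_common <- length(fit$common_candidates)

  if (!is.null(config$annotation) && !is.null(config$qtls)) {
    ann <- read_gene_annotation(config$annotation,
                                config$annotation_format)
    qt <- read_qtl_table(config$qtls)
    st0 <- if ("meiosis" %in% names(fit$specific)) "meiosis" else
      names(fit$specific)[1]
    sel <- ann[ann$gene_id %in% fit$specific[[st0]], , drop = FALSE]
    hits <- map_genes_to_qtls(sel, qt)
    write_tsv_commented(hits, outp("qtl_hits.tsv"), params)
    write_tsv_commented(summarize_by_trait(hits),
                        outp("qtl_trait_summary.tsv"), params)
    manifest$stages$qtl_hits <- nrow(hits)
  }
  if (!is.null(config$terms)) {
    ann <- read_term_annotation(config$terms)
    for (st in names(fit$specific)) {
      set <- intersect(fit$specific[[st]], fit$universe[[st]])
      res <- enrich(set, ann, fit$universe[[st]])
      write_tsv_commented(res, outp(sprintf("enrichment_%s.tsv", st)),
                          params)
      manifest$stages[[paste0("enrichment_", st)]] <- nrow(res)
    }
  }
  if (!is.null(config$traits)) {
    tr <- read_trait_table(config$traits)
    het <- trait_heterosis_table(tr)
    write_tsv_commented(het, outp("heterosis.tsv"), params)
    manifest$stages$heterosis <- nrow(het)
  }
  if (!is.null(config$cytology)) {
    cy <- read.delim(config$cytology, comment.char = "#",
                     stringsAsFactors = FALSE)
    need <- c("genotype", "stage", "normal", "total")
    miss <- setdiff(need, names(cy))
    if (length(miss))
      stop("cytology table missing column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    rows <- lapply(split(cy, cy$genotype), function(d) {
      fr <- normal_cell_frequency(d)
      data.frame(genotype = d$genotype[1],
                 stage = c(names(fr$per_stage), "overall"),
                 frequency_percent = c(unname(fr$per_stage), fr$overall),
                 stringsAsFactors = FALSE)
    })
    cyt <- do.call(rbind, rows); rownames(cyt) <- NULL
    write_tsv_commented(cyt, outp("cytology_frequencies.tsv"), params)
    manifest$stages$cytology <- nrow(cyt)
  }

  jsonlite::write_json(manifest, outp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  invisible(manifest)
}

#' Write a simulated experiment bundle to disk
#'
#' Convenience wrapper for testing the pipeline end to end: simulates an
#' experiment plus annotation, QTLs and a term annotation, and writes every
#' file [run_pipeline()] consumes.
#'
#' @param dir output directory.
#' @param config a [sim_config()].
#' @return a [pipeline_config()] pointing at the written files.
#' @export
write_sim_bundle <- function(dir, config = sim_config(n_genes = 500)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_experiment(config)
  write_count_matrix(sim$counts, file.path(dir, "counts.tsv"))
  write_design(sim$design, file.path(dir, "design.tsv"))
  ann <- generate_annotation(config$n_genes, seed = config$seed)
  write_gene_annotation(ann, file.path(dir, "genes.gff3"), "gff3")
  qt <- generate_qtls(c("pollen fertility", "1000-grain weight"), 20,
                      seed = config$seed)
  write_qtl_table(qt, file.path(dir, "qtls.tsv"))
  write_tsv_commented(sim$truth, file.path(dir, "truth.tsv"))
  # random term annotation over the simulated genes
  terms <- with_seed(config$seed, {
    data.frame(term_id = sprintf("TERM:%03d", sample.int(40,
                 config$n_genes * 2, replace = TRUE)),
               gene_id = sample(rownames(sim$counts), config$n_genes * 2,
                                replace = TRUE),
               stringsAsFactors = FALSE)
  })
  write_tsv_commented(unique(terms), file.path(dir, "terms.tsv"))
  pipeline_config(counts = file.path(dir, "counts.tsv"),
                  design = file.path(dir, "design.tsv"),
                  annotation = file.path(dir, "genes.gff3"),
                  qtls = file.path(dir, "qtls.tsv"),
                  terms = file.path(dir, "terms.tsv"),
                  seed = config$seed,
                  outdir = file.path(dir, "out"))
}
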