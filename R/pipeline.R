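#' Run the full analysis pipeline on a synthetic study
#'
#' Executes the whole inference chain on data from the synthetic generator:
#' genotype simulation and array-style variant QC, multi-condition expression
#' simulation, optional expression outlier removal, per-stimulus differential
#' expression and DEG classification, per-condition cis-eQTL mapping with the
#' beta-approximated permutation pass, response-eQTL (e2QTL) z-tests, GWAS
#' summary simulation, colocalization at the planted locus and assembly of
#' the trait-association table. Every table is written as a deterministic
#' TSV/JSON under `out_dir` together with a run manifest, so two runs with
#' identical configuration and seed produce byte-identical outputs.
#'
#' @param config A [simulation_config()], or a path to a YAML file of
#'   `simulation_config()` arguments.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for the analysis stages (the generator uses
#'   `config$seed`).
#' @param n_expr_factors Hidden expression factors for [prepare_expression()].
#'   Default 5.
#' @param n_genotype_pcs Genotype PCs used as covariates. Default 3.
#' @param n_perm_min,n_perm_max Permutation bounds for the eQTL pass.
#' @param window cis window half-width. Default 1e6.
#' @param alpha e2QTL Bonferroni significance level. Default 0.05.
#' @param r2_min LD threshold for the GWAS overlap. Default 0.7.
#' @param gwas_effect,gwas_n Causal effect (phenotype SD per allele) and
#'   cohort size of the simulated GWAS trait. Defaults 0.15 and 10000.
#' @param outlier_qc Run expression outlier detection and drop flagged
#'   samples. Default: TRUE when `config$n_outliers > 0`.
#' @return (Invisibly) a list with every intermediate result and the paths of
#'   the written files.
#' @export
run_pipeline <- function(config, out_dir, seed = 1L,
                         n_expr_factors = 5, n_genotype_pcs = 3,
                         n_perm_min = 1000, n_perm_max = 10000,
                         window = 1e6, alpha = 0.05, r2_min = 0.7,
                         gwas_effect = 0.15, gwas_n = 10000,
                         outlier_qc = NULL) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stopf("reading a YAML config requires the yaml package")
    }
    config <- do.call(simulation_config, yaml::read_yaml(config))
  }
  if (!inherits(config, "sim_config")) stopf("config must come from simulation_config()")
  if (is.null(outlier_qc)) outlier_qc <- config$n_outliers > 0
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(...) file.path(out_dir, ...)

  g0 <- simulate_genotypes(config)
  qc <- variant_qc(g0, maf_min = 0.05, call_rate_min = 0.97, hwe_p_min = 1e-4)
  g <- qc$genotypes
  write_dosage_tsv(g, pth("genotypes_qc.tsv"))

  sim <- simulate_expression(g, config)
  expr <- sim$expression
  conditions <- config$conditions
  ctrl <- conditions[1]
  stimuli <- conditions[-1]
  genes <- expr[[ctrl]]$genes
  .write_tsv(genes, pth("gene_annotation.tsv"))

  if (outlier_qc) {
    for (s in stimuli) {
      od <- expression_outlier_detection(expr[[ctrl]], expr[[s]], seed = seed)
      bad <- od$outliers
      for (cn in c(ctrl, s)) {
        keep <- !(expr[[cn]]$samples$sample_id %in% bad)
        if (!all(keep)) {
          expr[[cn]] <- expression_set(expr[[cn]]$counts[, keep, drop = FALSE],
                                       expr[[cn]]$genes,
                                       expr[[cn]]$samples[keep, , drop = FALSE])
        }
      }
    }
  }

  de <- list()
  for (s in stimuli) {
    counts <- cbind(expr[[ctrl]]$counts, expr[[s]]$counts)
    group <- factor(c(expr[[ctrl]]$samples$condition, expr[[s]]$samples$condition),
                    levels = c(ctrl, s))
    norm <- normalize_counts(counts)
    de[[s]] <- fit_de(norm$log_cpm, group)
    .write_tsv(as.data.frame(de[[s]]), pth(sprintf("de_%s.tsv", s)))
  }
  degs <- classify_degs(de)
  .write_tsv(degs$classification, pth("deg_classification.tsv"))
  .write_tsv(degs$condition_summary, pth("deg_summary.tsv"))

  pcs <- genotype_pca(g, n_genotype_pcs)
  prepared <- list()
  eqtl <- list()
  for (i in seq_along(conditions)) {
    cn <- conditions[i]
    donors <- expr[[cn]]$samples$donor
    gc <- g
    gc$dosage <- g$dosage[donors, , drop = FALSE]
    cov <- cbind(sex = expr[[cn]]$samples$sex, pcs[donors, , drop = FALSE])
    prepared[[cn]] <- prepare_expression(expr[[cn]], covariates = cov,
                                         n_expr_factors = n_expr_factors)
    eqtl[[cn]] <- map_cis_eqtl(gc, prepared[[cn]], genes, window = window,
                               n_perm_min = n_perm_min, n_perm_max = n_perm_max,
                               seed = seed + i)
    .write_tsv(as.data.frame(eqtl[[cn]]), pth(sprintf("eqtl_%s.tsv", cn)))
  }

  e2 <- list()
  for (s in stimuli) {
    donors <- intersect(expr[[ctrl]]$samples$donor, expr[[s]]$samples$donor)
    gc <- g
    gc$dosage <- g$dosage[donors, , drop = FALSE]
    pc <- prepared[[ctrl]]
    ps <- prepared[[s]]
    pc$expr <- pc$expr[match(paste0(ctrl, "_", donors),
                             expr[[ctrl]]$samples$sample_id), , drop = FALSE]
    ps$expr <- ps$expr[match(paste0(s, "_", donors),
                             expr[[s]]$samples$sample_id), , drop = FALSE]
    e2[[s]] <- map_response_eqtl(gc, pc, ps, eqtl[[ctrl]], eqtl[[s]],
                                 condition = s, alpha = alpha)
  }
  e2_all <- do.call(rbind, lapply(e2, as.data.frame))
  .write_tsv(e2_all, pth("e2qtl.tsv"))

  truth <- sim$truth
  coloc <- NULL
  gwas <- NULL
  associations <- NULL
  if (!is.null(truth$eqtl) && nrow(truth$eqtl)) {
    causal <- truth$eqtl$variant_id[1]
    causal_gene <- truth$eqtl$gene_id[1]
    gwas <- simulate_gwas_summary(g, causal, effect = gwas_effect, n = gwas_n,
                                  trait = "trait1", seed = seed + 31L)
    write_gwas_tsv(gwas, pth("gwas_trait1.tsv"))
    truth$gwas_causal <- data.frame(trait = "trait1", variant_id = causal,
                                    effect = gwas_effect, stringsAsFactors = FALSE)
    nominal_ctrl <- map_cis_nominal(g, prepared[[ctrl]], genes,
                                    window = window)
    loc <- nominal_ctrl[nominal_ctrl$gene_id == causal_gene, , drop = FALSE]
    if (nrow(loc)) {
      coloc <- coloc_abf(data.frame(variant_id = loc$variant_id,
                                    beta = loc$slope, se = loc$se,
                                    stringsAsFactors = FALSE),
                         gwas[, c("variant_id", "beta", "se")])
      jsonlite::write_json(list(gene_id = causal_gene,
                                pp = as.list(coloc$summary),
                                ratio_h4_h3 = coloc$ratio_h4_h3,
                                n_variants = coloc$n_variants),
                           pth("coloc.json"), auto_unbox = TRUE, digits = NA)
    }
    hit <- gwas[which.min(gwas$p), , drop = FALSE]
    gwas_hits <- data.frame(variant_id = hit$variant_id, trait = "trait1",
                            p = hit$p, stringsAsFactors = FALSE)
    assoc <- list()
    for (s in stimuli) {
      assoc[[s]] <- suppressWarnings(
        gwas_overlap(eqtl[[s]], e2[[s]], de[[s]], gwas_hits, g, genes,
                     condition = s, r2_min = r2_min, window = window))
    }
    associations <- do.call(rbind, assoc)
    rownames(associations) <- NULL
    .write_tsv(as.data.frame(associations), pth("trait_associations.tsv"))
  }

  manifest <- list(
    package = "stimqtl",
    version = as.character(utils::packageVersion("stimqtl")),
    seed = seed,
    config = config[!vapply(config, is.function, logical(1)) &
                      names(config) != "planted_eqtl"],
    thresholds = list(window = window, alpha = alpha, r2_min = r2_min,
                      maf_min = 0.05, call_rate_min = 0.97,
                      hwe_p_min_array = 1e-4, hwe_p_min_eqtl = 1e-6,
                      n_perm_min = n_perm_min, n_perm_max = n_perm_max)
  )
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA)

  invisible(list(genotypes = g, qc_report = qc$report, expression = expr,
                 truth = truth, de = de, degs = degs, prepared = prepared,
                 eqtl = eqtl, e2qtl = e2, gwas = gwas, coloc = coloc,
                 associations = associations, out_dir = out_dir))
}
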