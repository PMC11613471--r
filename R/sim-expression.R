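#' Construct an expression set (counts + annotation + sample covariates)
#'
#' Light container for one condition's gene-level counts. Counts are a genes x
#' samples integer matrix; `genes` carries the annotation needed for cis-eQTL
#' mapping (chrom, 1-based TSS, strand) and `samples` the per-sample
#' covariates (donor, condition, sex, batch).
#'
#' @param counts genes x samples numeric matrix (nonnegative).
#' @param genes data.frame with at least gene_id, chrom, tss, strand.
#' @param samples data.frame with at least sample_id, donor, condition.
#' @return An `expression_set`.
#' @export
expression_set <- function(counts, genes, samples) {
  if (!is.matrix(counts) || any(counts < 0, na.rm = TRUE)) {
    stopf("counts must be a nonnegative matrix")
  }
  if (nrow(counts) != nrow(genes)) stopf("gene annotation does not match counts")
  if (ncol(counts) != nrow(samples)) stopf("sample table does not match counts")
  rownames(counts) <- genes$gene_id
  colnames(counts) <- samples$sample_id
  structure(list(counts = counts, genes = genes, samples = samples,
                 lib_size = colSums(counts)),
            class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf("Expression set: %d genes x %d samples (condition %s, median depth %.3g)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$samples$condition), collapse = "/"),
              stats::median(x$lib_size)))
  invisible(x)
}

#' Simulate multi-condition expression with planted effects
#'
#' Draws negative-binomial counts for every condition of the paired design.
#' Per-gene baseline abundances and per-sample library sizes set the mean;
#' true DEGs in each stimulus receive a log2 fold change whose sign is
#' negative with the configured per-stimulus repressed fraction (emulating
#' the global transcriptional repression of genotoxic stress); planted
#' cis-eQTL act multiplicatively on the mean as `exp(slope * dosage)` with
#' condition-specific slopes, so stimulus slopes can attenuate relative to
#' control. Optional corrupted samples support outlier-QC testing.
#'
#' @param genotypes `genotype_matrix` whose donors are the expression donors.
#' @param config A [simulation_config()].
#' @return List with `expression` (named list of `expression_set`, one per
#'   condition) and `truth` (class `ground_truth`: planted eQTL slopes, DE
#'   status/log2FC, corrupted samples).
#' @export
simulate_expression <- function(genotypes, config) {
  if (!inherits(config, "sim_config")) stopf("config must come from simulation_config()")
  g <- as_genotype_matrix(genotypes)
  n <- nrow(g$dosage)
  if (n != config$n_donors) {
    stopf("genotype matrix has %d donors but config expects %d", n, config$n_donors)
  }
  n_genes <- config$n_genes
  conditions <- config$conditions
  stimuli <- conditions[-1]

  with_seed(config$seed + 1L, {
    pos_range <- range(g$variants$pos)
    genes <- data.frame(
      gene_id = sprintf("g%04d", seq_len(n_genes)),
      chrom = "1",
      tss = as.integer(round(stats::runif(n_genes,
                                          max(1, pos_range[1] - 5e5),
                                          pos_range[2] + 5e5))),
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      stringsAsFactors = FALSE
    )

    planted <- config$planted_eqtl
    if (is.null(planted) && config$n_eqtl > 0) {
      eg <- sample(n_genes, min(config$n_eqtl, n_genes))
      planted <- do.call(rbind, lapply(eg, function(i) {
        cis <- which(g$variants$chrom == genes$chrom[i] &
                       abs(g$variants$pos - genes$tss[i]) <= 1e6)
        if (length(cis) == 0L) return(NULL)
        v <- g$variants$variant_id[cis[sample.int(length(cis), 1)]]
        data.frame(gene_id = genes$gene_id[i], variant_id = v,
                   condition = conditions,
                   slope = c(config$eqtl_slope,
                             rep(config$eqtl_slope * config$eqtl_attenuation,
                                 length(stimuli))),
                   stringsAsFactors = FALSE)
      }))
    }
    if (!is.null(planted)) {
      if (!all(planted$gene_id %in% genes$gene_id)) stopf("planted gene absent from annotation")
      if (!all(planted$variant_id %in% g$variants$variant_id)) {
        stopf("planted variant absent from genotype matrix")
      }
      if (!all(planted$condition %in% conditions)) stopf("planted condition unknown")
    }

    # baseline relative abundance (heavy-tailed) and per-gene sex effect
    rel <- stats::rgamma(n_genes, shape = 0.5)
    rel <- rel / sum(rel)
    sex <- stats::rbinom(n, 1, 0.5)
    sex_genes <- sample(n_genes, max(1, round(0.05 * n_genes)))
    sex_beta <- stats::setNames(rep(0, n_genes), genes$gene_id)
    sex_beta[sex_genes] <- stats::rnorm(length(sex_genes), 0, 0.2)

    # true DE assignment: shared core + stimulus-specific genes
    n_de <- round(config$de_fraction * n_genes)
    n_core <- round(config$de_shared * n_de)
    core <- sample(n_genes, n_core)
    de_truth <- NULL
    de_sets <- list()
    for (s in stimuli) {
      extra <- sample(setdiff(seq_len(n_genes), core), max(0, n_de - n_core))
      idx <- c(core, extra)
      if (length(idx) == 0L) {
        de_sets[[s]] <- stats::setNames(numeric(0), character(0))
        next
      }
      lfc <- abs(stats::rnorm(length(idx), config$de_logfc_location,
                              config$de_logfc_scale))
      down <- stats::rbinom(length(idx), 1,
                            config$repressed_fraction[[s]]) == 1
      lfc[down] <- -lfc[down]
      de_sets[[s]] <- stats::setNames(lfc, genes$gene_id[idx])
      de_truth <- rbind(de_truth, data.frame(
        gene_id = genes$gene_id[idx], condition = s,
        status = ifelse(down, "down", "up"), log2fc = lfc,
        stringsAsFactors = FALSE))
    }

    dos <- g$dosage
    dos[is.na(dos)] <- rep(colMeans(dos, na.rm = TRUE), each = n)[is.na(dos)]

    size <- 1 / config$nb_dispersion
    batch <- sample(1:2, n, replace = TRUE)
    outlier_truth <- NULL
    expr <- list()
    eqtl_truth <- NULL
    for (cond in conditions) {
      lib <- stats::rlnorm(n, log(config$mean_depth), config$depth_sd_log)
      # log-mean per gene x sample
      logmu <- matrix(log(rel), n_genes, n, dimnames = list(genes$gene_id, NULL))
      logmu <- logmu + rep(log(lib), each = n_genes)
      logmu <- logmu + outer(sex_beta, sex) * log(2)
      if (cond != conditions[1] && length(de_sets[[cond]])) {
        lfc <- de_sets[[cond]]
        logmu[names(lfc), ] <- logmu[names(lfc), ] + lfc * log(2)
      }
      pl <- planted[planted$condition == cond, , drop = FALSE]
      if (!is.null(pl) && nrow(pl)) {
        for (k in seq_len(nrow(pl))) {
          logmu[pl$gene_id[k], ] <- logmu[pl$gene_id[k], ] +
            pl$slope[k] * dos[, pl$variant_id[k]]
        }
        eqtl_truth <- rbind(eqtl_truth, pl)
      }
      if (config$n_outliers > 0 && cond != conditions[1]) {
        out_idx <- sample(n, config$n_outliers)
        logmu[, out_idx] <- logmu[, out_idx] +
          matrix(stats::rnorm(n_genes * length(out_idx), 0, 3),
                 n_genes, length(out_idx))
        outlier_truth <- rbind(outlier_truth, data.frame(
          condition = cond,
          sample_id = sprintf("%s_%s", cond, rownames(dos)[out_idx]),
          stringsAsFactors = FALSE))
      }
      counts <- matrix(stats::rnbinom(n_genes * n, mu = exp(logmu), size = size),
                       n_genes, n)
      samples <- data.frame(
        sample_id = sprintf("%s_%s", cond, rownames(dos)),
        donor = rownames(dos), condition = cond,
        sex = sex, batch = batch, stringsAsFactors = FALSE)
      expr[[cond]] <- expression_set(counts, genes, samples)
    }

    truth <- structure(list(eqtl = eqtl_truth, de = de_truth,
                            outlier_samples = outlier_truth,
                            gwas_causal = NULL),
                       class = "ground_truth")
    list(expression = expr, truth = truth)
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("Ground truth: %d planted eQTL records, %d DE records, %d corrupted samples\n",
              if (is.null(x$eqtl)) 0L else nrow(x$eqtl),
              if (is.null(x$de)) 0L else nrow(x$de),
              if (is.null(x$outlier_samples)) 0L else nrow(x$outlier_samples)))
  invisible(x)
}
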