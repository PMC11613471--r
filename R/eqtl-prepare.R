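#' Rank-based inverse-normal transform
#'
#' Maps values to normal quantiles `qnorm((r - 0.5)/n)` of their ranks
#' (average ranks for ties), so any monotone distortion of the input yields
#' the same transformed vector.
#'
#' @param x Numeric vector.
#' @return Transformed vector, same length/names.
#' @export
inverse_normal_transform <- function(x) {
  stats::qnorm((rank(x, ties.method = "average") - 0.5) / length(x))
}

#' Prepare an expression matrix for cis-eQTL mapping
#'
#' GTEx-style preparation: expression filtering and TMM log-CPM, per-gene
#' rank-based inverse-normal transform across samples, estimation of hidden
#' expression factors as the top PCs of the transformed matrix (a PEER
#' substitute), and residualization on the combined covariates (user-supplied
#' covariates such as sex and genotype PCs, plus the expression factors).
#'
#' @param counts `expression_set` or genes x samples count matrix.
#' @param covariates Optional samples x q matrix/data.frame (sex, genotype
#'   PCs, ...).
#' @param n_expr_factors Number of expression PCs to include. Default 15.
#' @param cpm_min,min_frac Expression filter passed to [normalize_counts()].
#' @param rank_normalize Apply the inverse-normal transform. Default TRUE.
#' @return Class `prepared_expression`: list with `expr` (samples x genes,
#'   residualized and centred), `covariates` (design incl. intercept),
#'   `n_covariates` (columns beyond the intercept), `kept_genes`.
#' @export
prepare_expression <- function(counts, covariates = NULL, n_expr_factors = 15,
                               cpm_min = 1, min_frac = 0.2,
                               rank_normalize = TRUE) {
  norm <- normalize_counts(counts, cpm_min = cpm_min, min_frac = min_frac)
  Y <- t(norm$log_cpm)                       # samples x genes
  n <- nrow(Y)
  if (rank_normalize) Y <- apply(Y, 2, inverse_normal_transform)
  C <- matrix(1, n, 1, dimnames = list(rownames(Y), "intercept"))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stopf("covariate rows do not match samples")
    C <- cbind(C, covariates)
  }
  k <- min(n_expr_factors, n - 1, ncol(Y))
  if (k > 0) {
    Yc <- sweep(Y, 2, colMeans(Y))
    sv <- La.svd(Yc, nu = k, nv = 0)
    factors <- sv$u %*% diag(sv$d[seq_len(k)], k)
    colnames(factors) <- paste0("ExprPC", seq_len(k))
    C <- cbind(C, factors)
  }
  qr_c <- qr(C)
  if (qr_c$rank < ncol(C)) stopf("covariates are collinear (with the intercept)")
  resid <- qr.resid(qr_c, Y)
  resid <- sweep(resid, 2, colMeans(resid))   # re-centre (guards rounding)
  structure(list(expr = resid, covariates = C,
                 n_covariates = ncol(C) - 1L,
                 kept_genes = colnames(resid)),
            class = "prepared_expression")
}

#' @export
print.prepared_expression <- function(x, ...) {
  cat(sprintf("Prepared expression: %d samples x %d genes (%d covariates projected out)\n",
              nrow(x$expr), ncol(x$expr), x$n_covariates))
  invisible(x)
}

#' Enumerate cis gene-variant pairs
#'
#' A pair is included when gene and variant share a chromosome and the
#' variant lies within `window` bp of the gene's transcription start site
#' (inclusive). Distances are signed as `pos - tss` regardless of strand.
#' Genes without a TSS are skipped with a warning.
#'
#' @param genes data.frame: gene_id, chrom, tss (1-based).
#' @param variants data.frame: variant_id, chrom, pos (1-based).
#' @param window Window half-width in bp. Default 1e6.
#' @return data.frame: gene_id, variant_id, distance.
#' @export
cis_pairs <- function(genes, variants, window = 1e6) {
  miss <- is.na(genes$tss)
  if (any(miss)) {
    warning(sprintf("%d gene(s) without TSS skipped", sum(miss)))
    genes <- genes[!miss, , drop = FALSE]
  }
  out <- lapply(seq_len(nrow(genes)), function(i) {
    sel <- variants$chrom == genes$chrom[i] &
      abs(variants$pos - genes$tss[i]) <= window
    if (!any(sel)) return(NULL)
    data.frame(gene_id = genes$gene_id[i],
               variant_id = variants$variant_id[sel],
               distance = variants$pos[sel] - genes$tss[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), variant_id = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
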