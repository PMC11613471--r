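#' Nominal cis-eQTL scan for one gene
#'
#' Simple linear regression of a prepared (residualized) expression vector on
#' each variant's dosage. Covariates are assumed to have been projected out
#' already; the t-test uses `n - 2 - df_adjust` degrees of freedom, where
#' `df_adjust` can account for the projected covariates. Missing dosages are
#' mean-imputed; zero-variance variants are skipped.
#'
#' @param y Numeric expression vector (one gene, samples in genotype order).
#' @param dosages samples x variants dosage matrix.
#' @param df_adjust Extra degrees of freedom removed (covariate count).
#'   Default 0.
#' @return data.frame: variant_id, slope, se, r, p.
#' @export
nominal_scan <- function(y, dosages, df_adjust = 0) {
  if (!is.matrix(dosages)) dosages <- as.matrix(dosages)
  n <- length(y)
  if (nrow(dosages) != n) stopf("dosage rows do not match expression length")
  if (n < 10) stopf("need at least 10 samples")
  if (anyNA(dosages)) {
    mu <- colMeans(dosages, na.rm = TRUE)
    idx <- which(is.na(dosages))
    dosages[idx] <- mu[(idx - 1) %/% n + 1]
  }
  xc <- sweep(dosages, 2, colMeans(dosages))
  sxx <- colSums(xc^2)
  ok <- sxx > 0
  yc <- y - mean(y)
  syy <- sum(yc^2)
  sxy <- colSums(xc * yc)
  df <- n - 2 - df_adjust
  slope <- se <- p <- r <- rep(NA_real_, ncol(dosages))
  slope[ok] <- sxy[ok] / sxx[ok]
  rss <- pmax(syy - sxy[ok]^2 / sxx[ok], 0)
  se[ok] <- sqrt(rss / df / sxx[ok])
  r[ok] <- if (syy > 0) sxy[ok] / sqrt(sxx[ok] * syy) else 0
  tt <- ifelse(se[ok] > 0, slope[ok] / se[ok],
               ifelse(slope[ok] == 0, 0, Inf))
  p[ok] <- 2 * stats::pt(-abs(tt), df = df)
  out <- data.frame(variant_id = colnames(dosages) %||%
                      paste0("v", seq_len(ncol(dosages))),
                    slope = slope, se = se, r = r, p = p,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[ok, , drop = FALSE]
}

# method-of-moments init + maximum-likelihood Beta(a, b) fit
.fit_beta <- function(x) {
  x <- pmin(pmax(x, 1e-12), 1 - 1e-12)
  m <- mean(x); v <- stats::var(x)
  if (!is.finite(v) || v <= 0) return(c(a = 1, b = 1))
  common <- m * (1 - m) / v - 1
  init <- c(max(m * common, 1e-3), max((1 - m) * common, 1e-3))
  nll <- function(lp) -sum(stats::dbeta(x, exp(lp[1]), exp(lp[2]), log = TRUE))
  fit <- tryCatch(stats::optim(log(init), nll), error = function(e) NULL)
  if (is.null(fit) || fit$convergence != 0 || any(!is.finite(fit$par))) {
    return(c(a = init[1], b = init[2]))
  }
  c(a = exp(fit$par[1]), b = exp(fit$par[2]))
}

#' Permutation pass with beta approximation for one gene
#'
#' Permutes the gene's expression vector, records the minimum nominal
#' p-value across the cis variants for each permutation, and calibrates the
#' observed minimum against a Beta(a, b) distribution fitted to the permuted
#' minima by maximum likelihood (method-of-moments fallback). Runs
#' `n_perm_min` permutations first and extends to `n_perm_max` when fewer
#' than 10 permuted minima reach the observed minimum (adaptive scheme).
#' Also reports the direct permutation p-value `(1 + hits)/(1 + n_perm)`.
#'
#' @param y Prepared expression vector.
#' @param dosages samples x cis-variants dosage matrix.
#' @param distance Optional signed TSS distances (for top-variant
#'   tie-breaking: smaller |distance|, then lexicographic id).
#' @param n_perm_min,n_perm_max Permutation bounds (1000 and 10000 by
#'   default; `n_perm_min` below 100 is a configuration error).
#' @param seed Integer seed, or NULL to use the current RNG stream.
#' @param df_adjust Degrees-of-freedom adjustment, as in [nominal_scan()].
#' @return Class `perm_pass`: list with `top` (best-variant row), `a`, `b`,
#'   `n_perm`, `p_perm_beta`, `p_perm_direct`, `perm_min_p`.
#' @export
permutation_pass <- function(y, dosages, distance = NULL,
                             n_perm_min = 1000, n_perm_max = 10000,
                             seed = NULL, df_adjust = 0) {
  if (n_perm_min < 100) stopf("n_perm_min must be at least 100")
  if (n_perm_max < n_perm_min) stopf("n_perm_max must be >= n_perm_min")
  obs <- nominal_scan(y, dosages, df_adjust = df_adjust)
  if (nrow(obs) == 0) stopf("no usable cis variant (all zero-variance)")
  if (!is.null(distance)) {
    obs$distance <- distance[match(obs$variant_id, colnames(dosages))]
  } else {
    obs$distance <- NA_real_
  }
  ord <- order(obs$p, abs(obs$distance), obs$variant_id)
  top <- obs[ord[1], , drop = FALSE]
  n <- length(y)
  df <- n - 2 - df_adjust
  X <- dosages[, obs$variant_id, drop = FALSE]
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X))
    X[idx] <- mu[(idx - 1) %/% n + 1]
  }
  Xn <- sweep(X, 2, colMeans(X))
  Xn <- sweep(Xn, 2, sqrt(colSums(Xn^2)), "/")
  yn <- y - mean(y)
  if (sum(yn^2) == 0) stopf("constant expression vector")
  yn <- yn / sqrt(sum(yn^2))
  r2_to_p <- function(r2) {
    r2 <- pmin(r2, 1 - 1e-14)
    2 * stats::pt(-sqrt(r2 * df / (1 - r2)), df = df)
  }
  minp_batch <- function(B) {
    P <- vapply(seq_len(B), function(i) sample.int(n), integer(n))
    R <- crossprod(Xn, matrix(yn[P], n, B))
    r2 <- R[1, ]^2
    if (nrow(R) > 1) for (v in 2:nrow(R)) r2 <- pmax(r2, R[v, ]^2)
    r2_to_p(r2)
  }
  # observed minimum through the identical max-|r| transform, so observed
  # and permuted minima are exactly comparable
  p_obs <- r2_to_p(max(crossprod(Xn, yn)^2))
  with_seed(seed, {
    pm <- minp_batch(n_perm_min)
    hits <- sum(pm <= p_obs)
    if (hits < 10 && n_perm_max > n_perm_min) {
      pm <- c(pm, minp_batch(n_perm_max - n_perm_min))
      hits <- sum(pm <= p_obs)
    }
    ab <- .fit_beta(pm)
    structure(list(
      top = top,
      a = unname(ab["a"]), b = unname(ab["b"]),
      n_perm = length(pm),
      p_perm_beta = stats::pbeta(p_obs, ab["a"], ab["b"]),
      p_perm_direct = (1 + hits) / (1 + length(pm)),
      perm_min_p = pm
    ), class = "perm_pass")
  })
}

#' @export
print.perm_pass <- function(x, ...) {
  cat(sprintf("Permutation pass: top %s p=%.3g, beta(%.2f, %.2f) on %d perms -> p_perm=%.3g\n",
              x$top$variant_id, x$top$p, x$a, x$b, x$n_perm, x$p_perm_beta))
  invisible(x)
}

#' Gene-level cis-eQTL mapping for one condition
#'
#' Applies the eQTL-stage variant filters (MAF > 5% and exact-HWE p > 1e-6
#' by default), enumerates cis pairs within the window, runs the
#' beta-approximated permutation pass per gene, and attaches gene-level
#' q-values across all tested genes.
#'
#' @param genotypes `genotype_matrix` (donors x variants).
#' @param prepared `prepared_expression` for one condition, samples in the
#'   genotype donor order.
#' @param genes Gene annotation data.frame (gene_id, chrom, tss).
#' @param window cis window half-width. Default 1e6.
#' @param maf_min,hwe_p_min,call_rate_min eQTL-stage variant filters.
#' @param n_perm_min,n_perm_max Permutation bounds.
#' @param seed Integer seed driving all permutations.
#' @param qval_method Passed to [compute_qvalues()].
#' @param df_adjust Degrees-of-freedom adjustment for the nominal tests.
#' @return Class `eqtl_result` data.frame: gene_id, variant_id, distance,
#'   slope, se, p_nominal, a, b, n_perm, p_perm_beta, p_perm_direct, qval.
#' @export
map_cis_eqtl <- function(genotypes, prepared, genes, window = 1e6,
                         maf_min = 0.05, hwe_p_min = 1e-6, call_rate_min = 0,
                         n_perm_min = 1000, n_perm_max = 10000, seed = 1L,
                         qval_method = "BH", df_adjust = 0) {
  g <- as_genotype_matrix(genotypes)
  qc <- variant_qc(g, maf_min = maf_min, call_rate_min = call_rate_min,
                   hwe_p_min = hwe_p_min)
  g <- qc$genotypes
  genes <- genes[genes$gene_id %in% prepared$kept_genes, , drop = FALSE]
  pairs <- cis_pairs(genes, g$variants, window = window)
  if (nrow(pairs) == 0) stopf("no cis pairs after filtering")
  rows <- list()
  with_seed(seed, {
    for (gid in unique(pairs$gene_id)) {
      pg <- pairs[pairs$gene_id == gid, , drop = FALSE]
      dos <- g$dosage[, pg$variant_id, drop = FALSE]
      y <- prepared$expr[, gid]
      pp <- tryCatch(
        permutation_pass(y, dos,
                         distance = pg$distance[match(colnames(dos), pg$variant_id)],
                         n_perm_min = n_perm_min, n_perm_max = n_perm_max,
                         seed = NULL, df_adjust = df_adjust),
        error = function(e) NULL)
      if (is.null(pp)) next
      rows[[gid]] <- data.frame(
        gene_id = gid, variant_id = pp$top$variant_id,
        distance = pp$top$distance, slope = pp$top$slope, se = pp$top$se,
        p_nominal = pp$top$p, a = pp$a, b = pp$b, n_perm = pp$n_perm,
        p_perm_beta = unname(pp$p_perm_beta),
        p_perm_direct = pp$p_perm_direct,
        stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stopf("no gene could be mapped")
  out$qval <- compute_qvalues(out$p_perm_beta, method = qval_method)
  rownames(out) <- NULL
  class(out) <- c("eqtl_result", "data.frame")
  attr(out, "n_tested") <- nrow(out)
  out
}

#' Nominal cis-eQTL statistics for all pairs in one condition
#'
#' Full per-pair nominal scan (no permutations), used for e2QTL slope
#' refits, colocalization inputs and regional plots.
#'
#' @inheritParams map_cis_eqtl
#' @return data.frame: gene_id, variant_id, distance, slope, se, r, p.
#' @export
map_cis_nominal <- function(genotypes, prepared, genes, window = 1e6,
                            maf_min = 0.05, hwe_p_min = 1e-6,
                            call_rate_min = 0, df_adjust = 0) {
  g <- as_genotype_matrix(genotypes)
  qc <- variant_qc(g, maf_min = maf_min, call_rate_min = call_rate_min,
                   hwe_p_min = hwe_p_min)
  g <- qc$genotypes
  genes <- genes[genes$gene_id %in% prepared$kept_genes, , drop = FALSE]
  pairs <- cis_pairs(genes, g$variants, window = window)
  if (nrow(pairs) == 0) stopf("no cis pairs after filtering")
  rows <- lapply(unique(pairs$gene_id), function(gid) {
    pg <- pairs[pairs$gene_id == gid, , drop = FALSE]
    dos <- g$dosage[, pg$variant_id, drop = FALSE]
    sc <- nominal_scan(prepared$expr[, gid], dos, df_adjust = df_adjust)
    if (nrow(sc) == 0) return(NULL)
    sc$gene_id <- gid
    sc$distance <- pg$distance[match(sc$variant_id, pg$variant_id)]
    sc
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stopf("no usable cis pair")
  rownames(out) <- NULL
  out[, c("gene_id", "variant_id", "distance", "slope", "se", "r", "p")]
}
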