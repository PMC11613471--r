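#' Trimmed mean of M-values (TMM) scaling factors
#'
#' Library-composition normalization for count matrices. The reference sample
#' is the one whose 75th count-fraction percentile is closest to the mean
#' across samples. For every other sample, gene-wise log2 ratios (M) and
#' average log2 abundances (A) against the reference are double-trimmed
#' (30% of M, 5% of A by default) and the remaining M values averaged with
#' inverse asymptotic-variance weights; the factor is 2 to that mean.
#' Factors are rescaled to have geometric mean 1.
#'
#' @param counts genes x samples nonnegative matrix.
#' @param lib_size Optional library sizes (default column sums).
#' @param logratio_trim Fraction of extreme M values trimmed each side via
#'   total 2x; default 0.3 (keep central 40%).
#' @param sum_trim Fraction of extreme A values trimmed; default 0.05.
#' @param do_weighting Use delta-method precision weights. Default TRUE.
#' @return Numeric vector of scaling factors (one per sample).
#' @export
tmm_factors <- function(counts, lib_size = NULL, logratio_trim = 0.3,
                        sum_trim = 0.05, do_weighting = TRUE) {
  if (is.null(lib_size)) lib_size <- colSums(counts)
  if (any(lib_size == 0)) stopf("sample with all-zero counts")
  f75 <- apply(counts, 2, function(x) stats::quantile(x, 0.75)) / lib_size
  ref <- which.min(abs(f75 - mean(f75)))
  xr <- counts[, ref]
  lr <- lib_size[ref]
  f <- vapply(seq_len(ncol(counts)), function(s) {
    if (s == ref) return(1)
    x <- counts[, s]; ls <- lib_size[s]
    ok <- x > 0 & xr > 0
    if (!any(ok)) return(1)
    M <- log2((x[ok] / ls) / (xr[ok] / lr))
    A <- 0.5 * log2((x[ok] / ls) * (xr[ok] / lr))
    w <- (ls - x[ok]) / (ls * x[ok]) + (lr - xr[ok]) / (lr * xr[ok])
    # edgeR-style double trimming by rank
    nk <- length(M)
    loM <- floor(nk * logratio_trim) + 1; hiM <- nk + 1 - loM
    loA <- floor(nk * sum_trim) + 1; hiA <- nk + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    if (!any(keep)) return(1)
    fm <- if (do_weighting) {
      sum(M[keep] / w[keep]) / sum(1 / w[keep])
    } else {
      mean(M[keep])
    }
    if (!is.finite(fm)) fm <- 0
    2^fm
  }, numeric(1))
  f / exp(mean(log(f)))
}

#' Log2 counts-per-million with library-size-scaled prior count
#'
#' `log2((x + pc_s) / (lib_s + 2 pc_s) * 1e6)` where the prior count for
#' sample s is `prior_count * lib_s / mean(lib)`, so exactly proportional
#' samples map to identical log-CPM columns.
#'
#' @param counts genes x samples matrix.
#' @param lib_size Effective library sizes (default column sums; multiply by
#'   TMM factors for normalized values).
#' @param prior_count Prior count before lib-size scaling. Default 0.5.
#' @return genes x samples log2-CPM matrix.
#' @export
log_cpm <- function(counts, lib_size = NULL, prior_count = 0.5) {
  if (is.null(lib_size)) lib_size <- colSums(counts)
  pc <- prior_count * lib_size / mean(lib_size)
  t(log2((t(counts) + pc) / (lib_size + 2 * pc) * 1e6))
}

#' Normalize counts to filtered log2-CPM
#'
#' TMM scaling followed by log2-CPM with a 0.5 prior count. Genes expressed
#' below `cpm_min` (raw CPM) in fewer than `min_frac` of samples are removed.
#'
#' @param counts `expression_set` or genes x samples matrix.
#' @param cpm_min CPM threshold for the expression filter. Default 1.
#' @param min_frac Minimum fraction of samples above `cpm_min`. Default 0.2.
#' @param prior_count Prior count for the log transform. Default 0.5.
#' @param filter Apply the expression filter. Default TRUE.
#' @return Class `normalized_counts`: list with `log_cpm` (filtered genes x
#'   samples), `factors`, `lib_size`, `kept_genes`.
#' @export
normalize_counts <- function(counts, cpm_min = 1, min_frac = 0.2,
                             prior_count = 0.5, filter = TRUE) {
  mat <- if (inherits(counts, "expression_set")) counts$counts else counts
  if (ncol(mat) < 2) stopf("need at least 2 samples")
  lib <- colSums(mat)
  if (any(lib == 0)) stopf("sample with all-zero counts")
  factors <- tmm_factors(mat, lib)
  eff_lib <- lib * factors
  keep <- rep(TRUE, nrow(mat))
  if (filter) {
    cpm_raw <- t(t(mat) / lib * 1e6)
    keep <- rowMeans(cpm_raw > cpm_min) >= min_frac
  }
  lcpm <- log_cpm(mat[keep, , drop = FALSE], eff_lib, prior_count)
  structure(list(log_cpm = lcpm, factors = factors, lib_size = lib,
                 kept_genes = rownames(mat)[keep]),
            class = "normalized_counts")
}

#' @export
print.normalized_counts <- function(x, ...) {
  cat(sprintf("Normalized counts: %d genes x %d samples (TMM factors %.3f-%.3f)\n",
              nrow(x$log_cpm), ncol(x$log_cpm),
              min(x$factors), max(x$factors)))
  invisible(x)
}
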