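#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditional on the observed allele counts
#' (Levene-Haldane distribution of the heterozygote count). The p-value is
#' the sum of the probabilities of all heterozygote counts compatible with
#' the allele counts whose probability does not exceed that of the observed
#' configuration.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (nonnegative; at least one positive).
#' @return Exact two-sided p-value in \[0, 1\].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stopf("genotype counts must be nonnegative")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stopf("at least one genotype must be observed")
  n_a <- 2 * n_aa + n_Aa                 # count one allele; symmetry handles the other
  n_rare <- min(n_a, 2 * n - n_a)
  # attainable heterozygote counts share the parity of the rare allele count
  hets <- seq.int(n_rare %% 2, n_rare, by = 2)
  if (length(hets) == 1L) return(1.0)    # monomorphic: single configuration
  # log P(h) up to the constant term: -log((n_rare-h)/2)! - log h! -
  #   log((n - (n_rare+h)/2)! ... ) + h*log 2
  logp <- vapply(hets, function(h) {
    hom_rare <- (n_rare - h) / 2
    hom_common <- n - hom_rare - h
    h * log(2) - lfactorial(hom_rare) - lfactorial(h) - lfactorial(hom_common)
  }, numeric(1))
  logp <- logp - logsumexp(logp)
  obs <- logp[match(n_Aa, hets)]
  sum(exp(logp[logp <= obs + 1e-12]))
}

#' Variant-level quality control
#'
#' Applies the array-style variant filters: keep variants with
#' `maf > maf_min`, `call_rate > call_rate_min` and exact-HWE
#' `p > hwe_p_min` (all strict inequalities). Removals are attributed to the
#' first failing filter in the order call rate, MAF, HWE.
#'
#' @param genotypes `genotype_matrix` or dosage matrix.
#' @param maf_min Minor allele frequency threshold. Default 0.05.
#' @param call_rate_min Call-rate threshold. Default 0.97.
#' @param hwe_p_min HWE p-value threshold. Default 1e-4 (use 1e-6 for the
#'   eQTL-stage filter).
#' @return List with `genotypes` (filtered `genotype_matrix`) and `report`
#'   (class `qc_report`).
#' @export
variant_qc <- function(genotypes, maf_min = 0.05, call_rate_min = 0.97,
                       hwe_p_min = 1e-4) {
  g <- as_genotype_matrix(genotypes)
  if (ncol(g$dosage) == 0L || nrow(g$dosage) == 0L) stopf("empty genotype matrix")
  if (maf_min < 0 || maf_min > 0.5) stopf("maf_min must lie in [0, 0.5]")
  if (call_rate_min < 0 || call_rate_min > 1) stopf("call_rate_min must lie in [0, 1]")
  if (hwe_p_min < 0 || hwe_p_min > 1) stopf("hwe_p_min must lie in [0, 1]")
  st <- variant_stats(g)
  fail_cr <- !(st$call_rate > call_rate_min)
  fail_maf <- !(st$maf > maf_min)
  fail_hwe <- !(st$hwe_p > hwe_p_min)
  first_fail <- rep(NA_character_, nrow(st))
  first_fail[fail_hwe] <- "hwe"
  first_fail[fail_maf] <- "maf"
  first_fail[fail_cr] <- "call_rate"
  keep <- is.na(first_fail)
  filtered <- g
  filtered$dosage <- g$dosage[, keep, drop = FALSE]
  filtered$variants <- g$variants[keep, , drop = FALSE]
  if (!is.null(filtered$sim)) {
    filtered$sim$freq <- filtered$sim$freq[keep]
    filtered$sim$block <- filtered$sim$block[keep]
  }
  report <- structure(list(
    n_input = nrow(st),
    n_pass = sum(keep),
    removals = c(call_rate = sum(first_fail == "call_rate", na.rm = TRUE),
                 maf = sum(first_fail == "maf", na.rm = TRUE),
                 hwe = sum(first_fail == "hwe", na.rm = TRUE)),
    thresholds = c(maf_min = maf_min, call_rate_min = call_rate_min,
                   hwe_p_min = hwe_p_min),
    variant_stats = cbind(st, pass = keep, removed_by = first_fail)
  ), class = "qc_report")
  list(genotypes = filtered, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report: %d/%d variants pass", x$n_pass, x$n_input))
  if (!is.null(x$removals)) {
    cat(sprintf(" (removed: %s)",
                paste(sprintf("%s=%d", names(x$removals), x$removals),
                      collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

#' Genotype principal components
#'
#' PCA of the mean-imputed, column-standardized dosage matrix, for use as
#' population-stratification covariates. Constant variants are dropped; the
#' sign of each component is fixed so its largest-magnitude loading is
#' positive.
#'
#' @param genotypes `genotype_matrix` or dosage matrix.
#' @param k Number of components (`k = 0` returns an empty score matrix).
#' @return samples x k matrix of PC scores (columns PC1..PCk).
#' @export
genotype_pca <- function(genotypes, k = 3) {
  g <- as_genotype_matrix(genotypes)
  d <- g$dosage
  if (k < 0) stopf("k must be nonnegative")
  if (k >= min(dim(d))) stopf("k must be smaller than both matrix dimensions")
  if (k == 0) {
    return(matrix(numeric(0), nrow(d), 0, dimnames = list(rownames(d), NULL)))
  }
  mu <- colMeans(d, na.rm = TRUE)
  d[is.na(d)] <- rep(mu, each = nrow(d))[is.na(d)]
  sds <- apply(d, 2, stats::sd)
  keep <- sds > 0
  if (!any(keep)) stopf("all variants are constant; PCA undefined")
  z <- scale(d[, keep, drop = FALSE])
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  k <- min(k, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    load <- pc$rotation[, j]
    s <- sign(load[which.max(abs(load))])
    if (s < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(g$dosage)
  scores
}

# two-component full-covariance Gaussian mixture EM in 2D, deterministic
# given the initial hard assignment
.gmm2_em <- function(x, init_cluster, max_iter = 200, tol = 1e-8) {
  n <- nrow(x)
  z <- cbind(init_cluster == 1, init_cluster == 2) * 1
  loglik_old <- -Inf
  comp_logdens <- function(mu, S) {
    S <- S + diag(1e-8, 2)
    ch <- chol(S)
    xc <- sweep(x, 2, mu)
    q <- backsolve(ch, t(xc), transpose = TRUE)
    -log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(q^2)
  }
  pars <- NULL
  for (it in seq_len(max_iter)) {
    w <- colSums(z) / n
    pars <- lapply(1:2, function(kk) {
      wk <- z[, kk] / sum(z[, kk])
      mu <- colSums(x * wk)
      xc <- sweep(x, 2, mu)
      S <- crossprod(xc * sqrt(wk), xc * sqrt(wk))
      list(mu = mu, S = S)
    })
    ld <- vapply(1:2, function(kk) {
      log(w[kk]) + comp_logdens(pars[[kk]]$mu, pars[[kk]]$S)
    }, numeric(n))
    m <- pmax(ld[, 1], ld[, 2])
    lse <- m + log(exp(ld[, 1] - m) + exp(ld[, 2] - m))
    z <- exp(ld - lse)
    loglik <- sum(lse)
    if (abs(loglik - loglik_old) < tol * (1 + abs(loglik))) break
    loglik_old <- loglik
  }
  list(weights = colSums(z) / n, pars = pars, posterior = z,
       logdens = lse, cluster = max.col(z))
}

.gmm2_density <- function(fit, x) {
  dens1 <- function(mu, S, w) {
    S <- S + diag(1e-8, 2)
    ch <- chol(S)
    xc <- sweep(x, 2, mu)
    q <- backsolve(ch, t(xc), transpose = TRUE)
    w * exp(-log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(q^2))
  }
  dens1(fit$pars[[1]]$mu, fit$pars[[1]]$S, fit$weights[1]) +
    dens1(fit$pars[[2]]$mu, fit$pars[[2]]$S, fit$weights[2])
}

#' Expression-based sample outlier detection
#'
#' Pools a control and a stimulated expression set, computes the top two PCs
#' of the log-CPM matrix, fits a two-component full-covariance Gaussian
#' mixture (k-means-style deterministic initialization), and flags samples
#' whose mixture density falls below a configurable quantile of the fitted
#' mixture's own density distribution, or whose cluster assignment does not
#' match their condition's dominant cluster. When the PC scores are
#' degenerate (no expression variation) no sample is flagged.
#'
#' @param counts_control,counts_stimulus `expression_set` objects sharing the
#'   gene universe.
#' @param density_quantile Density quantile below which a sample is an
#'   outlier. Default 0.001 (0.1%).
#' @param pattern_check Also flag condition/cluster mismatches (only applied
#'   when the two clusters are dominated by different conditions). Default TRUE.
#' @param seed Seed for the Monte-Carlo density quantile. Default 1.
#' @return List with `outliers` (sample ids), `flags` (per-sample data.frame),
#'   `scores` (PC coordinates), `cluster` assignments and a `report`
#'   (`qc_report`).
#' @export
expression_outlier_detection <- function(counts_control, counts_stimulus,
                                         density_quantile = 0.001,
                                         pattern_check = TRUE,
                                         seed = 1L) {
  stopifnot(inherits(counts_control, "expression_set"),
            inherits(counts_stimulus, "expression_set"))
  if (!identical(counts_control$genes$gene_id, counts_stimulus$genes$gene_id)) {
    stopf("expression sets must share the gene universe")
  }
  counts <- cbind(counts_control$counts, counts_stimulus$counts)
  condition <- c(counts_control$samples$condition,
                 counts_stimulus$samples$condition)
  sample_id <- c(counts_control$samples$sample_id,
                 counts_stimulus$samples$sample_id)
  n <- ncol(counts)
  if (n < 8) stopf("need at least 8 samples for outlier detection")
  lcpm <- log_cpm(counts)
  x <- t(lcpm)
  x <- sweep(x, 2, colMeans(x))
  sv <- La.svd(x, nu = 2, nv = 0)
  scores <- sv$u %*% diag(sv$d[1:2], 2)
  rownames(scores) <- sample_id
  colnames(scores) <- c("PC1", "PC2")
  flags <- data.frame(sample_id = sample_id, condition = condition,
                      cluster = NA_integer_, low_density = FALSE,
                      pattern_mismatch = FALSE, outlier = FALSE,
                      stringsAsFactors = FALSE)
  if (stats::sd(scores[, 1]) < 1e-10) {
    report <- structure(list(n_input = n, n_pass = n,
                             removals = c(low_density = 0L, pattern = 0L),
                             thresholds = c(density_quantile = density_quantile)),
                        class = "qc_report")
    return(list(outliers = character(0), flags = flags, scores = scores,
                cluster = rep(1L, n), report = report))
  }
  # deterministic, order-invariant k-means initialization: centers at the
  # samples nearest the 10th / 90th percentile of PC1
  q <- stats::quantile(scores[, 1], c(0.1, 0.9), names = FALSE)
  init_centers <- scores[c(which.min(abs(scores[, 1] - q[1])),
                           which.min(abs(scores[, 1] - q[2]))), , drop = FALSE]
  km <- suppressWarnings(stats::kmeans(scores, centers = init_centers))
  fit <- .gmm2_em(scores, km$cluster)
  dens <- .gmm2_density(fit, scores)
  thr <- with_seed(seed, {
    comp <- sample(1:2, 50000, replace = TRUE, prob = fit$weights)
    sim <- t(vapply(comp, function(kk) {
      S <- fit$pars[[kk]]$S + diag(1e-8, 2)
      fit$pars[[kk]]$mu + drop(stats::rnorm(2) %*% chol(S))
    }, numeric(2)))
    stats::quantile(.gmm2_density(fit, sim), density_quantile, names = FALSE)
  })
  flags$cluster <- fit$cluster
  flags$low_density <- dens < thr
  if (pattern_check) {
    # dominant cluster per condition; a sample not assigned to its own
    # condition's dominant cluster breaks the condition-cluster pattern.
    # When the clustering does not track condition at all (mismatch fraction
    # > 20%) the rule is uninformative and is disabled.
    tab <- table(condition, factor(fit$cluster, levels = 1:2))
    dominant <- stats::setNames(max.col(tab), rownames(tab))
    mism <- fit$cluster != dominant[condition]
    if (mean(mism) <= 0.2) flags$pattern_mismatch <- mism
  }
  flags$outlier <- flags$low_density | flags$pattern_mismatch
  report <- structure(list(
    n_input = n, n_pass = sum(!flags$outlier),
    removals = c(low_density = sum(flags$low_density),
                 pattern = sum(flags$pattern_mismatch & !flags$low_density)),
    thresholds = c(density_quantile = density_quantile)
  ), class = "qc_report")
  list(outliers = flags$sample_id[flags$outlier], flags = flags,
       scores = scores, cluster = fit$cluster, report = report)
}
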