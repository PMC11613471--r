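# Empirical-Bayes variance moderation: the prior df d0 and prior variance
# s0^2 are estimated by matching the first two moments of log residual
# variances to a scaled F distribution, then per-gene variances are shrunk
# toward s0^2 with weight d0/(d0+df).

.trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) / y < 1e-8) break
  }
  y
}

#' Squeeze per-gene variances toward a common prior
#'
#' @param s2 Per-gene residual variances.
#' @param df Residual degrees of freedom (scalar).
#' @return List with `df_prior` (possibly Inf), `var_prior`, `var_post`.
#' @keywords internal
squeeze_var <- function(s2, df) {
  ok <- s2 > 0
  if (!any(ok)) {
    return(list(df_prior = Inf, var_prior = 0, var_post = rep(0, length(s2))))
  }
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    df_prior <- Inf
    var_prior <- exp(emean)
  } else {
    df_prior <- 2 * .trigamma_inverse(evar)
    var_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
  }
  var_post <- if (is.finite(df_prior)) {
    (df_prior * var_prior + df * s2) / (df_prior + df)
  } else {
    rep(var_prior, length(s2))
  }
  list(df_prior = df_prior, var_prior = var_prior, var_post = var_post)
}

#' Moderated-t differential expression for one stimulus versus control
#'
#' Per-gene linear model of log2-CPM on a condition indicator plus optional
#' covariates, with empirical-Bayes shrinkage of residual variances toward a
#' common prior (moment-matching estimates of the prior df and variance) and
#' moderated t statistics on `df + df_prior` degrees of freedom.
#' Benjamini-Hochberg adjustment across genes.
#'
#' @param logcpm genes x samples log2-CPM matrix (e.g. from
#'   [normalize_counts()]).
#' @param group Factor or vector with two levels; the first level is the
#'   control and `log2fc` is stimulus minus control.
#' @param covariates Optional numeric matrix/data.frame of additional
#'   sample-level covariates.
#' @param prior_df Override the estimated prior df (use `Inf` to force the
#'   pooled common-variance limit). Default `NULL` (estimate).
#' @return Class `de_result` data.frame: gene_id, log2fc, t_mod, p, p_adj,
#'   mean_expr, with attributes `df_prior`, `var_prior`, `df_residual`.
#' @export
fit_de <- function(logcpm, group, covariates = NULL, prior_df = NULL) {
  group <- as.factor(group)
  if (nlevels(group) != 2) stopf("group must have exactly two levels")
  if (min(table(group)) < 2) stopf("need at least 2 samples per group")
  n <- ncol(logcpm)
  if (length(group) != n) stopf("group length does not match samples")
  X <- cbind(intercept = 1, condition = as.numeric(group == levels(group)[2]))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    X <- cbind(X, covariates)
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) stopf("design matrix is confounded (rank deficient)")
  p <- ncol(X)
  df <- n - p
  if (df < 1) stopf("no residual degrees of freedom")
  Y <- t(logcpm)                       # samples x genes
  coefs <- qr.coef(qr_x, Y)
  res <- qr.resid(qr_x, Y)
  s2 <- colSums(res^2) / df
  XtX_inv <- chol2inv(qr.R(qr_x))
  unscaled <- sqrt(XtX_inv[2, 2])
  lfc <- coefs[2, ]
  if (!is.null(prior_df) && is.infinite(prior_df)) {
    sq <- list(df_prior = Inf, var_prior = mean(s2), var_post = rep(mean(s2), length(s2)))
  } else {
    sq <- squeeze_var(s2, df)
    if (!is.null(prior_df)) {
      sq$df_prior <- prior_df
      sq$var_post <- (prior_df * sq$var_prior + df * s2) / (prior_df + df)
    }
  }
  se <- unscaled * sqrt(sq$var_post)
  tstat <- lfc / se
  df_total <- df + sq$df_prior
  pval <- if (is.finite(df_total)) {
    2 * stats::pt(-abs(tstat), df = df_total)
  } else {
    2 * stats::pnorm(-abs(tstat))
  }
  pval[se == 0] <- ifelse(lfc[se == 0] == 0, 1, 0)
  out <- data.frame(gene_id = rownames(logcpm),
                    log2fc = lfc,
                    t_mod = tstat,
                    p = pval,
                    p_adj = stats::p.adjust(pval, "BH"),
                    mean_expr = rowMeans(logcpm),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "df_prior") <- sq$df_prior
  attr(out, "var_prior") <- sq$var_prior
  attr(out, "df_residual") <- df
  class(out) <- c("de_result", "data.frame")
  out
}

#' Classify differentially expressed genes across stimuli
#'
#' A gene is significant in a stimulus when `p_adj < p_adj_max` and
#' `|log2fc| > abs_log2fc_min` (both strict). Genes significant in exactly
#' one stimulus are labelled `specific`; genes significant in two or more
#' stimuli (or, with `common_rule = "all"`, in every stimulus) are `common`;
#' the rest are `none`.
#'
#' @param de_list Named list of `de_result` objects (one per stimulus) over
#'   the same gene universe.
#' @param p_adj_max Adjusted-p threshold. Default 0.05.
#' @param abs_log2fc_min Absolute log2-fold-change threshold. Default 1.5.
#' @param common_rule `"two_or_more"` (default) or `"all"`.
#' @return List with `classification` (gene_id, n_significant,
#'   significant_in, label) and `condition_summary` (per stimulus: n_up,
#'   n_down, n_significant, frac_down).
#' @export
classify_degs <- function(de_list, p_adj_max = 0.05, abs_log2fc_min = 1.5,
                          common_rule = c("two_or_more", "all")) {
  common_rule <- match.arg(common_rule)
  if (is.null(names(de_list)) || any(names(de_list) == "")) {
    stopf("de_list must be a named list of de_result objects")
  }
  genes <- de_list[[1]]$gene_id
  for (d in de_list) {
    if (!setequal(d$gene_id, genes)) stopf("gene universes differ across conditions")
  }
  sig <- vapply(de_list, function(d) {
    idx <- match(genes, d$gene_id)
    d$p_adj[idx] < p_adj_max & abs(d$log2fc[idx]) > abs_log2fc_min
  }, logical(length(genes)))
  sig[is.na(sig)] <- FALSE
  n_sig <- rowSums(sig)
  n_cond <- length(de_list)
  label <- rep("none", length(genes))
  label[n_sig == 1] <- "specific"
  label[if (common_rule == "two_or_more") n_sig >= 2 else n_sig == n_cond] <- "common"
  classification <- data.frame(
    gene_id = genes,
    n_significant = n_sig,
    significant_in = apply(sig, 1, function(z) paste(names(de_list)[z], collapse = ",")),
    label = label,
    row.names = NULL, stringsAsFactors = FALSE)
  condition_summary <- do.call(rbind, lapply(names(de_list), function(cn) {
    d <- de_list[[cn]]
    idx <- match(genes, d$gene_id)
    s <- sig[, cn]
    down <- sum(s & d$log2fc[idx] < 0)
    up <- sum(s & d$log2fc[idx] > 0)
    data.frame(condition = cn, n_up = up, n_down = down,
               n_significant = sum(s),
               frac_down = if (sum(s) > 0) down / sum(s) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(classification = classification, condition_summary = condition_summary)
}
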