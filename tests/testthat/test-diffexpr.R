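test_that("TMM and log-CPM remove pure depth differences exactly", {
  withr::with_seed(21, {
    x1 <- stats::rnbinom(500, mu = 200, size = 10)
    counts <- cbind(s1 = x1, s2 = 2L * x1)
    rownames(counts) <- sprintf("g%03d", 1:500)
    f <- tmm_factors(counts)
    expect_equal(unname(f[1] / f[2]), 1, tolerance = 1e-12)
    lc <- log_cpm(counts)
    expect_equal(lc[, 1], lc[, 2], tolerance = 1e-12)
  })
})

test_that("trimming protects TMM factors from a single spiked gene", {
  withr::with_seed(22, {
    counts <- matrix(stats::rnbinom(1001 * 10, mu = 100, size = 20), 1001, 10)
    counts[1, 1:5] <- counts[1, 1:5] * 8L
    rownames(counts) <- sprintf("g%04d", 1:1001)
    colnames(counts) <- sprintf("s%02d", 1:10)
    f <- tmm_factors(counts)
    expect_true(all(abs(f - 1) < 0.02))
  })
})

test_that("TMM factors agree with the edgeR reference implementation", {
  withr::with_seed(23, {
    counts <- matrix(stats::rnbinom(2000 * 8, mu = exp(stats::rnorm(2000, 4, 1)),
                                    size = 5), 2000, 8)
    counts <- counts + 1L   # avoid zero-count genes entirely for a clean match
    ref <- edgeR::calcNormFactors(counts, method = "TMM")
    expect_equal(unname(tmm_factors(counts)), unname(ref), tolerance = 5e-4)
  })
})

test_that("all-zero gene yields a constant log-CPM row", {
  counts <- matrix(c(0L, 0L, 0L, 10L, 20L, 40L, 5L, 9L, 30L), 3, 3, byrow = TRUE)
  rownames(counts) <- c("zero", "a", "b")
  colnames(counts) <- c("s1", "s2", "s3")
  norm <- normalize_counts(counts, filter = FALSE)
  row <- norm$log_cpm["zero", ]
  expect_lt(diff(range(row)), 1e-10)
  expect_error(normalize_counts(cbind(counts, s4 = c(0L, 0L, 0L))), "all-zero")
})

test_that("moderated fit returns exact fold changes and calibrated nulls", {
  # exact group-mean difference with zero residual variance
  lc <- rbind(gene1 = rep(c(0, 1.5), each = 4),
              gene2 = rep(c(2, 2), each = 4))
  group <- factor(rep(c("CTRL", "UVC"), each = 4), levels = c("CTRL", "UVC"))
  de <- fit_de(lc, group)
  expect_equal(de$log2fc, c(1.5, 0), tolerance = 1e-12)

  # log2fc equals the difference of group means with no covariates
  withr::with_seed(24, {
    lc2 <- matrix(stats::rnorm(100 * 12), 100, 12,
                  dimnames = list(sprintf("g%03d", 1:100), NULL))
    g2 <- factor(rep(c("a", "b"), each = 6))
    de2 <- fit_de(lc2, g2)
    expect_equal(de2$log2fc,
                 unname(rowMeans(lc2[, 7:12]) - rowMeans(lc2[, 1:6])),
                 tolerance = 1e-12)
  })

  # type-I calibration on a pure-noise matrix
  withr::with_seed(25, {
    lc3 <- matrix(stats::rnorm(2000 * 40), 2000, 40,
                  dimnames = list(sprintf("g%04d", 1:2000), NULL))
    g3 <- factor(rep(c("a", "b"), each = 20))
    de3 <- fit_de(lc3, g3)
    expect_true(mean(de3$p < 0.05) >= 0.035 && mean(de3$p < 0.05) <= 0.065)
  })
})

test_that("infinite prior df collapses to the pooled-variance t-test", {
  withr::with_seed(26, {
    lc <- matrix(stats::rnorm(50 * 10), 50, 10,
                 dimnames = list(sprintf("g%02d", 1:50), NULL))
    group <- factor(rep(c("a", "b"), each = 5))
    de <- fit_de(lc, group, prior_df = Inf)
    X <- cbind(1, as.numeric(group == "b"))
    H <- solve(crossprod(X))
    res <- lc - tcrossprod(lc %*% X %*% H, X)
    s2 <- rowSums(res^2) / 8
    t_ref <- de$log2fc / sqrt(mean(s2) * H[2, 2])
    expect_equal(de$t_mod, unname(t_ref), tolerance = 1e-10)
  })
})

test_that("moderation matches limma's empirical-Bayes shrinkage", {
  withr::with_seed(27, {
    lc <- matrix(stats::rnorm(300 * 12, sd = rep(stats::rchisq(300, 4) / 4, 12)),
                 300, 12, dimnames = list(sprintf("g%03d", 1:300), NULL))
    group <- factor(rep(c("a", "b"), each = 6))
    de <- fit_de(lc, group)
    design <- stats::model.matrix(~group)
    fit <- limma::eBayes(limma::lmFit(lc, design))
    expect_equal(de$log2fc, unname(fit$coefficients[, 2]), tolerance = 1e-10)
    expect_equal(attr(de, "df_prior"), unname(fit$df.prior), tolerance = 1e-3)
    expect_equal(de$t_mod, unname(fit$t[, 2]), tolerance = 1e-4)
    expect_equal(de$p, unname(fit$p.value[, 2]), tolerance = 1e-4)
  })
})

test_that("fit_de rejects degenerate designs", {
  lc <- matrix(stats::rnorm(20), 2, 10)
  rownames(lc) <- c("g1", "g2")
  expect_error(fit_de(lc, rep("a", 10)), "two levels")
  expect_error(fit_de(lc, factor(rep(c("a", "b"), each = 5)),
                      covariates = as.numeric(rep(c(0, 1), each = 5))),
               "confounded")
})

test_that("DEG classification applies strict thresholds and labels", {
  mk <- function(genes, lfc, padj) {
    d <- data.frame(gene_id = genes, log2fc = lfc, t_mod = 0, p = padj,
                    p_adj = padj, mean_expr = 1)
    class(d) <- c("de_result", "data.frame")
    d
  }
  genes <- c("g1", "g2", "g3")
  de_list <- list(
    BPDE = mk(genes, c(2.0, 1.5, -3), c(0.01, 0.04, 0.2)),
    UVC = mk(genes, c(-2.5, 0.1, -3), c(0.001, 0.9, 0.01)))
  res <- classify_degs(de_list)
  cls <- res$classification
  expect_equal(cls$label[cls$gene_id == "g1"], "common")
  # boundary: p_adj = 0.04 but log2fc exactly 1.5 fails the strict >
  expect_equal(cls$label[cls$gene_id == "g2"], "none")
  expect_equal(cls$label[cls$gene_id == "g3"], "specific")
  expect_equal(cls$significant_in[cls$gene_id == "g3"], "UVC")
  # stricter all-conditions rule demotes genes shared by only some stimuli
  de_list3 <- c(de_list, list(MMS = mk(genes, c(3, 0, 0), c(0.5, 0.5, 0.5))))
  res3 <- classify_degs(de_list3, common_rule = "all")
  expect_equal(res3$classification$label,
               c("none", "none", "specific")[match(genes, res3$classification$gene_id)])
  # order invariance
  shuffle <- function(d) d[c(3, 1, 2), ]
  res_perm <- classify_degs(rev(lapply(de_list, shuffle)))
  expect_equal(res_perm$condition_summary[order(res_perm$condition_summary$condition), ],
               res$condition_summary[order(res$condition_summary$condition), ],
               ignore_attr = TRUE)
})

test_that("q-value helpers match the step-up definition", {
  withr::with_seed(28, {
    for (i in 1:25) {
      p <- stats::runif(sample(3:50, 1))
      expect_equal(compute_qvalues(p), bh_stepup_oracle(p), tolerance = 1e-12)
    }
  })
  expect_equal(compute_qvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(compute_qvalues(rep(1, 5)), rep(1, 5))
  p <- c(0.2, 0.01, 0.7, 0.04)
  expect_equal(order(compute_qvalues(p)), order(p))
  storey <- compute_qvalues(c(stats::runif(50), rep(0.001, 10)), "storey")
  expect_true(all(storey <= 1 & storey >= 0))
})
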