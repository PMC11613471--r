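# construct a small locus with controllable LD between the GWAS hit and the
# top eQTL variant
toy_locus <- function(seed = 71, flip = 30) {
  withr::with_seed(seed, {
    n <- 500
    v_top <- stats::rbinom(n, 2, 0.3)
    v_gwas <- v_top
    idx <- sample(n, flip)
    v_gwas[idx] <- stats::rbinom(flip, 2, 0.3)   # degrade LD
    d <- cbind(v_top = v_top, v_gwas = v_gwas)
    rownames(d) <- sprintf("D%03d", 1:n)
    g <- as_genotype_matrix(d)
    g$variants$pos <- c(1500000L, 1600000L)
    g
  })
}

mk_eqtl_row <- function(gene = "g1", variant = "v_top", qval = 0.01) {
  d <- data.frame(gene_id = gene, variant_id = variant, distance = 1000,
                  slope = -0.5, se = 0.1, p_nominal = 1e-8, a = 1, b = 30,
                  n_perm = 1000, p_perm_beta = 1e-4, p_perm_direct = 1e-3,
                  qval = qval, stringsAsFactors = FALSE)
  class(d) <- c("eqtl_result", "data.frame")
  d
}

mk_de_row <- function(gene = "g1", log2fc = -2.5, p_adj = 1e-6) {
  d <- data.frame(gene_id = gene, log2fc = log2fc, t_mod = -10, p = p_adj,
                  p_adj = p_adj, mean_expr = 5, stringsAsFactors = FALSE)
  class(d) <- c("de_result", "data.frame")
  d
}

mk_e2_row <- function(gene = "g1", variant = "v_top", significant = TRUE) {
  d <- data.frame(gene_id = gene, variant_id = variant, condition = "UVC",
                  slope_ctrl = -0.7, se_ctrl = 0.1, slope_stim = -0.05,
                  se_stim = 0.1, delta_slope = 0.65, z = 4.6, p = 4e-6,
                  p_bonf = 4e-4, significant = significant,
                  stringsAsFactors = FALSE)
  class(d) <- c("e2qtl_result", "data.frame")
  d
}

toy_genes <- data.frame(gene_id = "g1", chrom = "1", tss = 1400000L,
                        strand = "+", stringsAsFactors = FALSE)
toy_hits <- data.frame(variant_id = "v_gwas", trait = "traitX", p = 1e-9,
                       stringsAsFactors = FALSE)

test_that("GWAS overlap emits eQTL records passing every filter", {
  g <- toy_locus()
  r2 <- ld_r2(g$dosage[, "v_gwas"], g$dosage[, "v_top"])
  expect_gt(r2, 0.7)
  rec <- gwas_overlap(mk_eqtl_row(), NULL, mk_de_row(), toy_hits, g, toy_genes,
                      condition = "UVC")
  expect_equal(nrow(rec), 1)
  expect_equal(rec$association_class, "eqtl")
  expect_equal(rec$ld_r2, r2)
  # strict LD threshold: a threshold equal to the observed r2 excludes it
  expect_equal(nrow(gwas_overlap(mk_eqtl_row(), NULL, mk_de_row(), toy_hits,
                                 g, toy_genes, r2_min = r2)), 0)
  # weak DE excludes the eqtl class
  expect_equal(nrow(gwas_overlap(mk_eqtl_row(), NULL,
                                 mk_de_row(log2fc = -1.8), toy_hits, g,
                                 toy_genes)), 0)
  expect_equal(nrow(gwas_overlap(mk_eqtl_row(qval = 0.06), NULL, mk_de_row(),
                                 toy_hits, g, toy_genes)), 0)
  # sub-genome-wide GWAS hits are dropped on read
  weak_hit <- transform(toy_hits, p = 1e-6)
  expect_equal(nrow(gwas_overlap(mk_eqtl_row(), NULL, mk_de_row(), weak_hit,
                                 g, toy_genes)), 0)
})

test_that("significant e2QTL records bypass the DE filter", {
  g <- toy_locus()
  rec <- gwas_overlap(mk_eqtl_row(), mk_e2_row(), mk_de_row(log2fc = 0.1, p_adj = 0.99),
                      toy_hits, g, toy_genes, condition = "UVC")
  expect_equal(nrow(rec), 1)
  expect_equal(rec$association_class, "e2qtl")
  # but they still need eQTL significance and LD
  expect_equal(nrow(gwas_overlap(mk_eqtl_row(qval = 0.5), mk_e2_row(),
                                 NULL, toy_hits, g, toy_genes)), 0)
  expect_equal(nrow(gwas_overlap(mk_eqtl_row(), mk_e2_row(significant = FALSE),
                                 NULL, toy_hits, g, toy_genes)), 0)
  # unknown GWAS variants are skipped with a warning
  expect_warning(
    none <- gwas_overlap(mk_eqtl_row(), mk_e2_row(), NULL,
                         transform(toy_hits, variant_id = "v_missing"),
                         g, toy_genes),
    "absent")
  expect_equal(nrow(none), 0)
})

test_that("every emitted record passes an independent re-filter", {
  g <- toy_locus(seed = 72, flip = 10)
  eq <- rbind(mk_eqtl_row("g1"), mk_eqtl_row("g2", qval = 0.2),
              mk_eqtl_row("g3", variant = "v_gwas"))
  de <- rbind(mk_de_row("g1"), mk_de_row("g2"), mk_de_row("g3", log2fc = -1))
  e2 <- mk_e2_row("g3", variant = "v_gwas")
  genes <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "1",
                      tss = c(1400000L, 1450000L, 1700000L), strand = "+")
  rec <- gwas_overlap(eq, e2, de, toy_hits, g, genes, condition = "UVC")
  expect_gt(nrow(rec), 0)
  for (i in seq_len(nrow(rec))) {
    expect_gt(rec$ld_r2[i], 0.7)
    expect_lt(rec$qval[i], 0.05)
    if (rec$association_class[i] == "eqtl") {
      expect_lt(rec$de_p_adj[i], 0.05)
      expect_gt(abs(rec$de_log2fc[i]), 2)
    } else {
      expect_true(e2$significant[e2$gene_id == rec$gene_id[i]])
    }
  }
  # row-order invariance
  rec2 <- gwas_overlap(eq[c(3, 1, 2), ], e2, de[c(2, 3, 1), ], toy_hits,
                       g, genes, condition = "UVC")
  expect_equal(rec, rec2)
})

test_that("eQTL set comparison reports concordance and sign flips", {
  withr::with_seed(73, {
    a <- data.frame(gene_id = sprintf("g%02d", 1:20),
                    variant_id = sprintf("v%02d", 1:20),
                    slope = stats::rnorm(20))
    self <- compare_eqtl_sets(a, a)
    expect_equal(self$spearman, 1.0)
    expect_equal(self$n_opposite, 0)
    neg <- a
    neg$slope <- -neg$slope
    opp <- compare_eqtl_sets(a, neg)
    expect_equal(opp$spearman, -1.0)
    expect_equal(opp$n_opposite, 20)
    # exactly the planted sign flips are flagged
    b <- a
    flipped <- sprintf("g%02d", c(2, 5, 9, 13, 17))
    b$slope[b$gene_id %in% flipped] <- -b$slope[b$gene_id %in% flipped]
    res <- compare_eqtl_sets(a, b)
    expect_setequal(res$opposite_genes, flipped)
    expect_error(compare_eqtl_sets(a, transform(a, gene_id = paste0("x", gene_id))),
                 "no shared")
  })
})
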