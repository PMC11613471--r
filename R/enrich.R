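#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether its overlap with the selected genes is
#' larger than expected under hypergeometric sampling from the universe
#' (upper-tail `P(X >= overlap)`), with Benjamini-Hochberg correction across
#' sets. Genes outside the universe are ignored.
#'
#' @param selected Character vector of selected genes (e.g. significant DEGs).
#' @param gene_sets Named list of character vectors (or a single vector).
#' @param universe Character vector: the gene universe (typically all genes
#'   surviving the expression filter).
#' @return data.frame: set_id, set_size, overlap, expected, p, q.
#' @export
ora <- function(selected, gene_sets, universe) {
  if (length(universe) == 0) stopf("empty universe")
  if (!is.list(gene_sets)) gene_sets <- list(set1 = gene_sets)
  if (is.null(names(gene_sets))) names(gene_sets) <- paste0("set", seq_along(gene_sets))
  universe <- unique(universe)
  selected <- intersect(unique(selected), universe)
  N <- length(universe)
  k <- length(selected)
  out <- do.call(rbind, lapply(names(gene_sets), function(id) {
    set <- intersect(unique(gene_sets[[id]]), universe)
    K <- length(set)
    ov <- length(intersect(set, selected))
    p <- stats::phyper(ov - 1, K, N - K, k, lower.tail = FALSE)
    data.frame(set_id = id, set_size = K, overlap = ov,
               expected = k * K / N, p = p, stringsAsFactors = FALSE)
  }))
  out$q <- stats::p.adjust(out$p, "BH")
  rownames(out) <- NULL
  out
}

# weighted Kolmogorov-Smirnov running sum for one set over a descending
# ranking; returns the signed enrichment score and the running sum
.gsea_es <- function(order_scores, hit, weight = 1) {
  N <- length(order_scores)
  Nh <- sum(hit)
  if (Nh == 0) return(list(es = NA_real_, running = rep(0, N)))
  w <- abs(order_scores)^weight
  w[!hit] <- 0
  tot <- sum(w)
  p_hit <- if (tot > 0) cumsum(w) / tot else cumsum(hit) / Nh
  p_miss <- if (N > Nh) cumsum(!hit) / (N - Nh) else seq_len(N) / N
  running <- p_hit - p_miss
  i <- which.max(abs(running))
  list(es = running[i], running = running)
}

#' Gene-set enrichment analysis (weighted KS running sum)
#'
#' Genes are ranked by decreasing score; for each set, hits contribute
#' `|score|^weight` (normalized) to the running sum and misses subtract
#' `1/(N - Nh)`; the enrichment score (ES) is the maximum deviation from
#' zero. Significance comes from a gene-label permutation null: set
#' membership is reassigned at random `n_perm` times, the ES normalized by
#' the mean absolute permuted ES of the same sign (NES), and p-values
#' computed within the sign class, with BH correction across sets.
#' Sets with no overlap with the ranking are skipped with a warning.
#'
#' @param scores Named numeric vector: gene-level ranking statistic (no
#'   duplicated names).
#' @param gene_sets Named list of character vectors.
#' @param weight Exponent on `|score|` for hit increments. Default 1.
#' @param n_perm Number of label permutations. Default 1000.
#' @param seed Integer seed. Default 1.
#' @return data.frame: set_id, size, es, nes, p, q.
#' @export
gsea <- function(scores, gene_sets, weight = 1, n_perm = 1000, seed = 1L) {
  if (anyDuplicated(names(scores))) stopf("duplicate gene names in ranking")
  if (!is.list(gene_sets)) gene_sets <- list(set1 = gene_sets)
  if (is.null(names(gene_sets))) names(gene_sets) <- paste0("set", seq_along(gene_sets))
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  genes <- names(s)
  N <- length(s)
  with_seed(seed, {
    rows <- lapply(names(gene_sets), function(id) {
      set <- unique(gene_sets[[id]])
      hit <- genes %in% set
      Nh <- sum(hit)
      if (Nh == 0) {
        warning(sprintf("gene set '%s' has no overlap with the ranking; skipped", id))
        return(NULL)
      }
      es <- .gsea_es(s, hit, weight)$es
      perm_es <- vapply(seq_len(n_perm), function(i) {
        ph <- logical(N)
        ph[sample.int(N, Nh)] <- TRUE
        .gsea_es(s, ph, weight)$es
      }, numeric(1))
      same <- if (es >= 0) perm_es[perm_es >= 0] else perm_es[perm_es < 0]
      denom <- mean(abs(same))
      nes <- if (is.finite(denom) && denom > 0) es / denom else NA_real_
      p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
      data.frame(set_id = id, size = Nh, es = es, nes = nes, p = p,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) return(NULL)
    out$q <- stats::p.adjust(out$p, "BH")
    rownames(out) <- NULL
    out
  })
}
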