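#' Evaluate code with a temporarily fixed RNG state
#'
#' Sets the RNG seed for the duration of `code` and restores the caller's
#' RNG state afterwards, so simulation helpers are reproducible without
#' clobbering the session seed.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

#' Numerically stable log(sum(exp(x)))
#' @param x Numeric vector.
#' @return Scalar log-sum-exp.
#' @keywords internal
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg / Storey q-values for gene-level p-values
#'
#' Thin wrapper used for gene-level multiple-testing correction. The default
#' is Benjamini-Hochberg step-up adjustment; `method = "storey"` additionally
#' scales by the Storey null-proportion estimate pi0 evaluated at lambda = 0.5
#' (`pi0 = min(1, mean(p > 0.5) / 0.5)`), which is more powerful when many
#' genes are truly regulated but less stable for small gene counts.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param method `"BH"` (default) or `"storey"`.
#' @return Numeric vector of q-values, same order as `p`.
#' @export
compute_qvalues <- function(p, method = c("BH", "storey")) {
  method <- match.arg(method)
  if (length(p) == 0L) stopf("empty p-value vector")
  if (any(!is.na(p) & (p < 0 | p > 1))) stopf("p-values must lie in [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  if (method == "storey") {
    pi0 <- min(1, mean(p > 0.5, na.rm = TRUE) / 0.5)
    if (!is.finite(pi0) || pi0 <= 0) pi0 <- 1
    q <- pmin(1, pi0 * q)
  }
  q
}
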