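# Plain-text readers/writers for the pipeline's standard tables. All writers
# use tab separation, no quoting and "\n" line endings so repeated runs are
# byte-identical.

.write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
}

#' Write genotypes as a dosage TSV (variants x samples)
#'
#' First columns are variant metadata (variant_id, chrom, pos, ref, alt),
#' followed by one dosage column per sample.
#'
#' @param genotypes `genotype_matrix`.
#' @param path Output file.
#' @export
write_dosage_tsv <- function(genotypes, path) {
  g <- as_genotype_matrix(genotypes)
  d <- cbind(g$variants[, c("variant_id", "chrom", "pos", "ref", "alt")],
             as.data.frame(t(g$dosage)))
  .write_tsv(d, path)
  invisible(path)
}

#' Read a dosage TSV written by [write_dosage_tsv()]
#' @param path Input file.
#' @return A `genotype_matrix`.
#' @export
read_dosage_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- c("variant_id", "chrom", "pos", "ref", "alt")
  variants <- d[, meta_cols]
  variants$chrom <- as.character(variants$chrom)
  variants$block <- NA_integer_
  variants$freq <- NA_real_
  dosage <- t(as.matrix(d[, setdiff(names(d), meta_cols), drop = FALSE]))
  colnames(dosage) <- variants$variant_id
  structure(list(dosage = dosage, variants = variants, sim = NULL),
            class = "genotype_matrix")
}

#' Read genotypes from a VCF (GT field) into a dosage matrix
#'
#' Parses a VCF v4.x file with vcfR and converts GT calls to alt-allele
#' dosages (0/1/2; missing calls become NA).
#'
#' @param path VCF file (uncompressed or gzipped).
#' @return A `genotype_matrix`.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stopf("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- apply(gt, c(1, 2), function(x) {
    if (is.na(x)) return(NA_real_)
    a <- strsplit(x, "[/|]")[[1]]
    if (any(a == ".")) return(NA_real_)
    sum(as.numeric(a) > 0)
  })
  fix <- vcfR::getFIX(v)
  variants <- data.frame(
    variant_id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                        paste0(fix[, "CHROM"], ":", fix[, "POS"]), fix[, "ID"]),
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    block = NA_integer_, freq = NA_real_,
    stringsAsFactors = FALSE)
  dosage <- t(dos)
  colnames(dosage) <- variants$variant_id
  structure(list(dosage = dosage, variants = variants, sim = NULL),
            class = "genotype_matrix")
}

#' Write an expression set as counts / annotation / sample TSVs
#' @param es `expression_set`.
#' @param counts_path,genes_path,samples_path Output files (annotation and
#'   samples optional).
#' @export
write_expression_tsv <- function(es, counts_path, genes_path = NULL,
                                 samples_path = NULL) {
  .write_tsv(cbind(gene_id = rownames(es$counts), as.data.frame(es$counts)),
             counts_path)
  if (!is.null(genes_path)) .write_tsv(es$genes, genes_path)
  if (!is.null(samples_path)) .write_tsv(es$samples, samples_path)
  invisible(counts_path)
}

#' Read gene sets from a GMT file
#' @param path GMT file (set name, description, then member genes per line).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t")[[1]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t")[[1]][1], character(1))
  sets
}

#' Write GWAS summary statistics as TSV
#' @param gwas `gwas_summary` data.frame.
#' @param path Output file.
#' @export
write_gwas_tsv <- function(gwas, path) {
  .write_tsv(as.data.frame(gwas), path)
  invisible(path)
}

#' Read GWAS summary statistics from TSV
#' @param path Input file with columns variant_id, chrom, pos, effect_allele,
#'   other_allele, beta, se, p, n.
#' @param trait Trait label. Default "trait1".
#' @param type Trait type. Default "quant".
#' @return `gwas_summary` data.frame.
#' @export
read_gwas_tsv <- function(path, trait = "trait1", type = "quant") {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("variant_id", "beta", "se", "p")
  if (!all(need %in% names(d))) {
    stopf("GWAS TSV needs columns %s", paste(need, collapse = ", "))
  }
  attr(d, "trait") <- trait
  attr(d, "type") <- type
  class(d) <- c("gwas_summary", "data.frame")
  d
}
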