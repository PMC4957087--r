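#' Published chloroplast-insertion table for the sacred lotus mitochondrial
#' genome
#'
#' The 19 chloroplast-derived fragments reported for the 524,797-bp
#' *Nelumbo nucifera* mitochondrial genome (GenBank KR610474), as printed:
#' fragment number, length, genomic position and the chloroplast genes each
#' fragment carries. Shipped as a plain-text fixture; used to reproduce the
#' published totals (8,256 bp, 1.6% of the genome) without requiring the
#' accession itself.
#'
#' @return data.frame: no, length, start, end, genes_contained
#' @export
lotusFragmentTable <- function() {
  utils::read.delim(system.file("extdata", "lotus_mt_cp_fragments.tsv",
                                package = "mitoscan"),
                    stringsAsFactors = FALSE)
}

#' Published feature statistics for the sacred lotus mitochondrial genome
#'
#' The printed per-class base-pair totals for the 524,797-bp genome, used
#' to verify that [percentOfGenome()] reproduces every printed percentage.
#'
#' @return data.frame: category, count, total_bp, printed_percent
#' @export
lotusFeatureTable <- function() {
  data.frame(
    category = c("protein coding", "pseudogenes", "rRNA", "mt-derived tRNA",
                 "cp-derived tRNA", "ORF", "cis-spliced introns",
                 "repeats >500", "short repeats", "SSRs"),
    count = c(43L, 9L, 6L, 13L, 7L, 96L, 20L, 8L, 191L, 201L),
    total_bp = c(35651L, 5541L, 11407L, 1054L, 506L, 38062L, 39780L,
                 48898L, 16668L, 2628L),
    printed_percent = c(6.8, 1.1, 2.2, 0.2, 0.1, 7.3, 7.6, 9.3, 3.2, 0.5),
    stringsAsFactors = FALSE)
}

.LOTUS_MT_LEN <- 524797L
.LOTUS_GC_BP <- 252718L
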