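#' @importFrom Biostrings subseq letterFrequency xscat
NULL

#' Round half away from zero
#'
#' Fixed half-up rounding used for every printed statistic in the package
#' (base R `round()` rounds half to even). A tiny epsilon absorbs binary
#' floating-point representation error.
#'
#' @param x numeric
#' @param digits decimal places
#' @return rounded numeric
#' @export
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' GC content of a genome, percent to two decimals
#'
#' N positions count toward the length denominator but not toward G+C, so the
#' value matches a naive length-based computation.
#'
#' @param x a [Genome-class], DNAString or character sequence
#' @return percent, rounded half-up to 2 decimals
#' @examples
#' gcPercent(Genome("g", "GGCC"))  # 100
#' @export
gcPercent <- function(x) {
  if (is(x, "Genome")) x <- x@sequence
  if (is.character(x)) x <- DNAString(toupper(x))
  gc <- sum(letterFrequency(x, c("G", "C")))
  roundHalfUp(100 * gc / length(x), 2)
}

#' Percent of genome occupied by a feature class
#'
#' @param bp total feature length in bp
#' @param genome_len genome length in bp
#' @param digits decimal places (1 for summary-table percents)
#' @return percent, rounded half-up
#' @export
percentOfGenome <- function(bp, genome_len, digits = 1) {
  if (genome_len <= 0) stop("genome_len must be > 0")
  roundHalfUp(100 * bp / genome_len, digits)
}

#' Sequencing coverage depth
#'
#' Total read bp divided by genome length, rounded to the nearest integer.
#'
#' @param total_read_bp summed read length, bp
#' @param genome_len genome length, bp
#' @return integer depth
#' @export
coverageDepth <- function(total_read_bp, genome_len) {
  if (genome_len <= 0) stop("genome_len must be > 0")
  if (total_read_bp <= 0) stop("total_read_bp must be > 0")
  as.integer(roundHalfUp(total_read_bp / genome_len, 0))
}

#' Mean read length
#'
#' @param total_read_bp summed read length, bp
#' @param n_reads number of reads
#' @return mean length rounded to nearest integer bp
#' @export
meanReadLength <- function(total_read_bp, n_reads) {
  if (n_reads <= 0) stop("n_reads must be > 0")
  as.integer(roundHalfUp(total_read_bp / n_reads, 0))
}

#' Assembly validation accuracy
#'
#' Fraction of independently re-sequenced bases that match the assembly,
#' as a percent to three decimals.
#'
#' @param n_mismatches mismatching bases
#' @param validated_bp total re-sequenced bases
#' @return percent, 3 decimals
#' @export
validationAccuracy <- function(n_mismatches, validated_bp) {
  if (validated_bp <= 0) stop("validated_bp must be > 0")
  if (n_mismatches < 0 || n_mismatches > validated_bp)
    stop("n_mismatches must lie in [0, validated_bp]")
  roundHalfUp(100 * (validated_bp - n_mismatches) / validated_bp, 3)
}

#' Spliced coding sequence of a gene
#'
#' Concatenates the gene's exon sequences in coding order, reverse-
#' complementing exons on the `-` strand. Works identically for cis- and
#' trans-spliced genes since coding order is taken from the annotation.
#'
#' @param genome a [Genome-class]
#' @param ann an [AnnotationSet-class]
#' @param gene_id gene identifier
#' @return character: the spliced sequence (5'->3' of the coding strand)
#' @export
spliceCds <- function(genome, ann, gene_id) {
  ex <- geneExons(ann, gene_id)
  parts <- lapply(seq_along(ex), function(i) {
    s <- subseq(genome@sequence, start(ex)[i], end(ex)[i])
    if (as.character(strand(ex))[i] == "-") s <- reverseComplement(s)
    as.character(s)
  })
  paste(unlist(parts), collapse = "")
}

#' Spliced CDSs for many genes
#'
#' @param genome a [Genome-class]
#' @param ann an [AnnotationSet-class]
#' @param gene_ids genes to splice (default: all)
#' @return named character vector of spliced sequences
#' @export
spliceAllCds <- function(genome, ann, gene_ids = genes(ann)$gene_id) {
  out <- vapply(gene_ids, function(g) spliceCds(genome, ann, g), character(1))
  names(out) <- gene_ids
  out
}

#' Project a spliced-CDS position back to a genomic coordinate
#'
#' Inverse of [spliceCds()]: position `cds_pos` (1-based in the spliced
#' sequence) is mapped to the genome through the gene's exons in coding
#' order, accounting for strand.
#'
#' @param ann an [AnnotationSet-class]
#' @param gene_id gene identifier
#' @param cds_pos 1-based position in the spliced CDS
#' @return 1-based genomic position
#' @export
cdsToGenomic <- function(ann, gene_id, cds_pos) {
  ex <- geneExons(ann, gene_id)
  w <- width(ex)
  cum <- cumsum(w)
  vapply(cds_pos, function(p) {
    if (p < 1 || p > cum[length(cum)]) stop("cds_pos outside spliced CDS")
    i <- which(p <= cum)[1]
    off <- p - c(0, cum)[i] - 1L   # 0-based offset within exon i
    if (as.character(strand(ex))[i] == "-") end(ex)[i] - off else start(ex)[i] + off
  }, numeric(1))
}

#' Mask annotated features with N
#'
#' Replaces every position covered by an exon of a gene in the selected
#' categories with `N`; sequence length is preserved. This is the standard
#' preprocessing before searching a mitochondrial genome against the
#' chloroplast genome, so that conserved housekeeping genes shared by both
#' organelles do not produce hits.
#'
#' @param genome a [Genome-class]
#' @param ann an [AnnotationSet-class]
#' @param categories gene categories to mask (default: protein, tRNA, rRNA)
#' @return character: the masked sequence
#' @export
maskFeatures <- function(genome, ann, categories = c("protein", "tRNA", "rRNA")) {
  stopifnot(all(categories %in% .GENE_CATEGORIES))
  keep <- genes(ann)$gene_id[genes(ann)$category %in% categories]
  ex <- exons(ann)
  ex <- ex[mcols(ex)$gene_id %in% keep]
  s <- strsplit(genomeString(genome), "")[[1]]
  if (length(ex)) {
    red <- IRanges::reduce(IRanges::ranges(ex))
    for (i in seq_along(red))
      s[IRanges::start(red)[i]:IRanges::end(red)[i]] <- "N"
  }
  paste(s, collapse = "")
}

#' Total cis-spliced intron length from annotation geometry
#'
#' For every cis (non-trans-spliced) multi-exon gene, introns are the gaps
#' between genomically consecutive exons; their widths are summed.
#'
#' @param ann an [AnnotationSet-class]
#' @return list with `n_introns` and `total_bp`
#' @export
cisIntronStats <- function(ann) {
  g <- genes(ann)
  n <- 0L; bp <- 0L
  for (gid in g$gene_id[!g$trans_spliced]) {
    e <- exons(ann)[mcols(exons(ann))$gene_id == gid]
    if (length(e) < 2L) next
    o <- order(start(e))
    gaps <- start(e)[o][-1] - end(e)[o][-length(e)] - 1L
    n <- n + length(gaps)
    bp <- bp + sum(gaps)
  }
  list(n_introns = n, total_bp = bp)
}

#' Genome feature summary table
#'
#' Mirrors the canonical organelle-genome statistics table: GC percent and,
#' per feature class, a count, total bp and percent of genome (1 decimal).
#' Gene classes are derived from the annotation (exonic bp per category,
#' with tRNAs split by native/plastid origin); intron bp comes from
#' annotation geometry; repeat and SSR rows from the screen results when
#' supplied.
#'
#' @param genome a [Genome-class]
#' @param ann an [AnnotationSet-class]
#' @param repeats optional data.frame from [findLongRepeats()]
#' @param ssrs optional data.frame from [findSsrs()]
#' @param short_repeats optional data.frame of 20-500 bp repeats
#' @return list of class `GenomeSummary`: `genome_id`, `genome_length`,
#'   `gc_percent`, and `features` (data.frame category/count/total_bp/percent)
#' @export
summarizeGenome <- function(genome, ann, repeats = NULL, ssrs = NULL,
                            short_repeats = NULL) {
  gl <- genomeLength(genome)
  g <- genes(ann)
  ex <- exons(ann)
  exbp <- function(ids) {
    e <- ex[mcols(ex)$gene_id %in% ids]
    if (!length(e)) 0L else sum(width(IRanges::reduce(IRanges::ranges(e))))
  }
  row <- function(category, ids) {
    data.frame(category = category, count = length(ids),
               total_bp = exbp(ids), stringsAsFactors = FALSE)
  }
  rows <- rbind(
    row("protein coding", g$gene_id[g$category == "protein"]),
    row("pseudogenes",    g$gene_id[g$category == "pseudogene"]),
    row("rRNA",           g$gene_id[g$category == "rRNA"]),
    row("mt-derived tRNA", g$gene_id[g$category == "tRNA" & g$origin == "native"]),
    row("cp-derived tRNA", g$gene_id[g$category == "tRNA" & g$origin == "plastid_derived"]),
    row("ORF",            g$gene_id[g$category == "orf"]))
  ci <- cisIntronStats(ann)
  rows <- rbind(rows, data.frame(category = "cis-spliced introns",
                                 count = ci$n_introns, total_bp = ci$total_bp))
  repRow <- function(category, df, cols) {
    if (is.null(df) || !nrow(df)) {
      data.frame(category = category, count = 0L, total_bp = 0L)
    } else {
      ir <- IRanges::reduce(do.call(c, lapply(cols, function(cc)
        IRanges(df[[cc[1]]], df[[cc[2]]]))))
      data.frame(category = category, count = nrow(df),
                 total_bp = sum(IRanges::width(ir)))
    }
  }
  rows <- rbind(rows,
    repRow("repeats >500", repeats,
           list(c("start_a", "end_a"), c("start_b", "end_b"))),
    repRow("short repeats", short_repeats,
           list(c("start_a", "end_a"), c("start_b", "end_b"))),
    repRow("SSRs", ssrs, list(c("start", "end"))))
  rows$percent <- percentOfGenome(rows$total_bp, gl, 1)
  structure(list(genome_id = genomeId(genome), genome_length = gl,
                 gc_percent = gcPercent(genome), features = rows),
            class = "GenomeSummary")
}

#' @export
print.GenomeSummary <- function(x, ...) {
  cat(sprintf("Genome '%s': %d bp, GC %.2f%%\n", x$genome_id,
              x$genome_length, x$gc_percent))
  print(x$features, row.names = FALSE)
  invisible(x)
}

#' Write a genome summary as TSV
#' @param summary a `GenomeSummary` from [summarizeGenome()]
#' @param path output path
#' @export
writeGenomeSummaryTsv <- function(summary, path) {
  df <- summary$features
  df <- rbind(data.frame(category = "G + C", count = NA,
                         total_bp = NA, percent = summary$gc_percent), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
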