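#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges start end strand width seqnames
#' @importFrom IRanges IRanges
#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
NULL

## Coordinate convention used throughout the package: 1-based, fully inclusive
## intervals (GenBank style). Origin-crossing features on circular genomes are
## represented as ordered multi-segment exon lists, never as end < start.

#' Genome: a single circular- or linear-mapping nucleotide molecule
#'
#' Thin wrapper around a [Biostrings::DNAString] carrying an identifier and a
#' topology flag. Sequences are stored uppercase over the alphabet A/C/G/T/N.
#'
#' @slot id character scalar identifier.
#' @slot sequence a [Biostrings::DNAString].
#' @slot topology `"circular"` or `"linear"`.
#' @export
setClass("Genome",
  representation(id = "character", sequence = "DNAString", topology = "character"))

setValidity("Genome", function(object) {
  msg <- character()
  if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
    msg <- c(msg, "'id' must be a single non-empty string")
  if (length(object@sequence) < 1L)
    msg <- c(msg, "sequence must have length >= 1")
  if (!object@topology %in% c("circular", "linear"))
    msg <- c(msg, "topology must be 'circular' or 'linear'")
  bad <- setdiff(unique(strsplit(as.character(object@sequence), "")[[1]]),
                 c("A", "C", "G", "T", "N"))
  if (length(bad))
    msg <- c(msg, paste0("sequence contains letters outside A/C/G/T/N: ",
                         paste(bad, collapse = ",")))
  if (length(msg)) msg else TRUE
})

#' Construct a Genome
#'
#' @param id genome identifier.
#' @param sequence character or DNAString; lowercase input is uppercased.
#' @param topology `"circular"` (default for organelle assemblies) or `"linear"`.
#' @return a [Genome-class] object.
#' @examples
#' g <- Genome("toy", "acgtACGT", topology = "circular")
#' genomeLength(g)
#' @export
Genome <- function(id, sequence, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  if (is.character(sequence)) sequence <- DNAString(toupper(sequence))
  new("Genome", id = id, sequence = sequence, topology = topology)
}

#' @describeIn Genome-class genome identifier
#' @param x a Genome
#' @export
genomeId <- function(x) x@id

#' @describeIn Genome-class the sequence as a DNAString
#' @export
genomeSeq <- function(x) x@sequence

#' @describeIn Genome-class the sequence as a plain character string
#' @export
genomeString <- function(x) as.character(x@sequence)

#' @describeIn Genome-class genome length in bp
#' @export
genomeLength <- function(x) length(x@sequence)

#' @describeIn Genome-class topology flag
#' @export
topology <- function(x) x@topology

setMethod("show", "Genome", function(object) {
  cat(sprintf("Genome '%s': %s, %d bp, GC %.2f%%\n",
              object@id, object@topology, length(object@sequence),
              gcPercent(object)))
})

#' AnnotationSet: gene models on one genome
#'
#' Gene-level metadata lives in a data.frame (`gene_id`, `name`, `category`,
#' `origin`, `trans_spliced`); exon segments live in a
#' [GenomicRanges::GRanges] whose `gene_id` and `coding_order` metadata
#' columns tie each exon to its gene and give the order in which exons are
#' concatenated during splicing. Categories are `protein`, `tRNA`, `rRNA`,
#' `pseudogene`, `orf`; origins are `native` or `plastid_derived`.
#'
#' @slot genomeId identifier of the annotated genome.
#' @slot genomeLength length of the annotated genome (bp), used for validity.
#' @slot genes data.frame of gene-level fields.
#' @slot exons GRanges of exon segments.
#' @export
setClass("AnnotationSet",
  representation(genomeId = "character", genomeLength = "integer",
                 genes = "data.frame", exons = "GRanges"))

.GENE_CATEGORIES <- c("protein", "tRNA", "rRNA", "pseudogene", "orf")

setValidity("AnnotationSet", function(object) {
  msg <- character()
  g <- object@genes
  need <- c("gene_id", "name", "category", "origin", "trans_spliced")
  if (!all(need %in% names(g)))
    return(paste("genes data.frame must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(g$gene_id))
    msg <- c(msg, "duplicate gene_id in annotation")
  if (!all(g$category %in% .GENE_CATEGORIES))
    msg <- c(msg, "unknown gene category")
  if (!all(g$origin %in% c("native", "plastid_derived")))
    msg <- c(msg, "origin must be 'native' or 'plastid_derived'")
  ex <- object@exons
  if (length(ex)) {
    if (!all(mcols(ex)$gene_id %in% g$gene_id))
      msg <- c(msg, "exon with unknown gene_id")
    if (any(start(ex) < 1L) || any(end(ex) > object@genomeLength))
      msg <- c(msg, "exon outside genome bounds")
    ## exons of one gene must not overlap each other
    for (gid in unique(mcols(ex)$gene_id)) {
      e <- ex[mcols(ex)$gene_id == gid]
      if (length(e) > 1L) {
        o <- IRanges::findOverlaps(IRanges::ranges(e), IRanges::ranges(e))
        if (length(o) > length(e))
          msg <- c(msg, sprintf("overlapping exons within gene '%s'", gid))
        gi <- g[g$gene_id == gid, ]
        if (!isTRUE(gi$trans_spliced) &&
            length(unique(as.character(strand(e)))) > 1L)
          msg <- c(msg, sprintf("cis gene '%s' has exons on both strands", gid))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AnnotationSet
#'
#' @param genome the annotated [Genome-class] (supplies id and length).
#' @param genes data.frame with columns `gene_id`, `name`, `category`,
#'   `origin`, `trans_spliced`.
#' @param exons [GenomicRanges::GRanges] with metadata columns `gene_id` and
#'   `coding_order`.
#' @return an [AnnotationSet-class].
#' @export
AnnotationSet <- function(genome, genes, exons) {
  genes$gene_id <- as.character(genes$gene_id)
  genes$name <- as.character(genes$name)
  if (is.null(mcols(exons)$coding_order))
    mcols(exons)$coding_order <- NA_integer_
  new("AnnotationSet", genomeId = genomeId(genome),
      genomeLength = genomeLength(genome), genes = genes, exons = exons)
}

#' @describeIn AnnotationSet-class the gene-level data.frame
#' @param x an AnnotationSet
#' @export
genes <- function(x) x@genes

#' @describeIn AnnotationSet-class all exon segments as a GRanges
#' @export
exons <- function(x) x@exons

#' Exons of one gene, in coding order
#'
#' Exons are ordered by their `coding_order` attribute when present; otherwise
#' by genomic position (ascending on `+`, descending on `-`).
#'
#' @param x an [AnnotationSet-class]
#' @param gene_id gene identifier
#' @return GRanges of the gene's exons in coding order
#' @export
geneExons <- function(x, gene_id) {
  e <- x@exons[mcols(x@exons)$gene_id == gene_id]
  if (!length(e)) stop("no exons for gene '", gene_id, "'")
  co <- mcols(e)$coding_order
  if (!any(is.na(co))) {
    e[order(co)]
  } else {
    st <- as.character(strand(e))[1]
    e[order(start(e), decreasing = (st == "-"))]
  }
}

setMethod("show", "AnnotationSet", function(object) {
  tab <- table(object@genes$category)
  cat(sprintf("AnnotationSet on '%s': %d genes (%s), %d exon segments\n",
              object@genomeId, nrow(object@genes),
              paste(names(tab), tab, sep = "=", collapse = ", "),
              length(object@exons)))
})

#' PipelineConfig: thresholds for every analysis stage
#'
#' Defaults are the screening thresholds conventionally used for plant
#' organelle genomes: perfect SSRs require at least 10/5/4/3/3/3 units for
#' unit lengths 1..6; long repeats need alignment length > 500 bp at >= 99%
#' identity; chloroplast-derived fragment search uses a 70% identity floor
#' and e-value cutoff 1e-5; cross-species homolog presence requires >= 80%
#' identity over >= 90% of the fragment.
#'
#' @slot ssrMinUnits integer vector of length 6 (unit lengths 1..6).
#' @slot longRepeatMinLen minimum long-repeat alignment length (exclusive), bp.
#' @slot longRepeatMinIdentity long-repeat identity floor, fraction.
#' @slot mtptMinIdentity fragment-search identity floor, fraction.
#' @slot mtptMaxEvalue fragment-search e-value ceiling.
#' @slot homologMinIdentity homolog identity floor, fraction.
#' @slot homologMinCoverage homolog coverage floor, fraction.
#' @slot rngSeed integer seed driving all in-package randomness.
#' @export
setClass("PipelineConfig",
  representation(ssrMinUnits = "integer", longRepeatMinLen = "numeric",
                 longRepeatMinIdentity = "numeric", mtptMinIdentity = "numeric",
                 mtptMaxEvalue = "numeric", homologMinIdentity = "numeric",
                 homologMinCoverage = "numeric", rngSeed = "integer"))

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (length(object@ssrMinUnits) != 6L || any(object@ssrMinUnits < 1L))
    msg <- c(msg, "ssrMinUnits must be 6 counts >= 1")
  fr <- c(object@longRepeatMinIdentity, object@mtptMinIdentity,
          object@homologMinIdentity, object@homologMinCoverage)
  if (any(fr <= 0) || any(fr > 1))
    msg <- c(msg, "identity/coverage fractions must lie in (0, 1]")
  if (object@mtptMaxEvalue < 0) msg <- c(msg, "mtptMaxEvalue must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a PipelineConfig
#'
#' @param ssrMinUnits minimum SSR unit counts for unit lengths 1..6.
#' @param longRepeatMinLen long repeats must be strictly longer than this (bp).
#' @param longRepeatMinIdentity long-repeat identity floor.
#' @param mtptMinIdentity chloroplast-fragment identity floor.
#' @param mtptMaxEvalue chloroplast-fragment e-value ceiling.
#' @param homologMinIdentity homolog identity floor.
#' @param homologMinCoverage homolog coverage floor.
#' @param rngSeed integer seed for the synthetic-data generators.
#' @return a [PipelineConfig-class].
#' @examples
#' cfg <- PipelineConfig(rngSeed = 7)
#' cfg
#' @export
PipelineConfig <- function(ssrMinUnits = c(10L, 5L, 4L, 3L, 3L, 3L),
                           longRepeatMinLen = 500,
                           longRepeatMinIdentity = 0.99,
                           mtptMinIdentity = 0.70,
                           mtptMaxEvalue = 1e-5,
                           homologMinIdentity = 0.80,
                           homologMinCoverage = 0.90,
                           rngSeed = 1L) {
  new("PipelineConfig", ssrMinUnits = as.integer(ssrMinUnits),
      longRepeatMinLen = longRepeatMinLen,
      longRepeatMinIdentity = longRepeatMinIdentity,
      mtptMinIdentity = mtptMinIdentity, mtptMaxEvalue = mtptMaxEvalue,
      homologMinIdentity = homologMinIdentity,
      homologMinCoverage = homologMinCoverage, rngSeed = as.integer(rngSeed))
}

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig:\n")
  cat("  SSR min units (1-6nt):", paste(object@ssrMinUnits, collapse = ","), "\n")
  cat(sprintf("  long repeats: > %g bp at >= %g%% identity\n",
              object@longRepeatMinLen, 100 * object@longRepeatMinIdentity))
  cat(sprintf("  cp-fragment search: >= %g%% identity, e-value <= %g\n",
              100 * object@mtptMinIdentity, object@mtptMaxEvalue))
  cat(sprintf("  homolog presence: >= %g%% identity, >= %g%% coverage\n",
              100 * object@homologMinIdentity, 100 * object@homologMinCoverage))
  cat("  rngSeed:", object@rngSeed, "\n")
})

#' Config slots as a flat named list (for manifests and logging)
#' @param cfg a [PipelineConfig-class]
#' @return named list of all threshold values
#' @export
configAsList <- function(cfg) {
  list(ssr_min_units = as.integer(cfg@ssrMinUnits),
       long_repeat_min_len = cfg@longRepeatMinLen,
       long_repeat_min_identity = cfg@longRepeatMinIdentity,
       mtpt_min_identity = cfg@mtptMinIdentity,
       mtpt_max_evalue = cfg@mtptMaxEvalue,
       homolog_min_identity = cfg@homologMinIdentity,
       homolog_min_coverage = cfg@homologMinCoverage,
       rng_seed = cfg@rngSeed)
}
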