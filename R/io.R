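#' @importFrom Biostrings readDNAStringSet writeXStringSet
#' @importFrom rtracklayer import export
#' @importFrom GenomeInfoDb seqlengths seqlengths<-
NULL

#' Read genomes from a FASTA file
#'
#' One [Genome-class] per record. Sequences are uppercased. Topology is taken
#' from a `topology=circular` token in the header line; the default is
#' linear.
#'
#' @param path FASTA file
#' @return list of [Genome-class], in file order
#' @export
readGenomeFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(readDNAStringSet(path, format = "fasta"),
                  error = function(e)
                    stop("malformed FASTA in '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  if (!length(set)) stop("empty FASTA file: ", path)
  lapply(seq_along(set), function(i) {
    header <- names(set)[i]
    toks <- strsplit(header, "\\s+")[[1]]
    topo <- "linear"
    tt <- grep("^topology=", toks, value = TRUE)
    if (length(tt) && sub("^topology=", "", tt[1]) == "circular")
      topo <- "circular"
    Genome(toks[1], toupper(as.character(set[[i]])), topology = topo)
  })
}

#' Write genomes to FASTA
#'
#' Headers carry a `topology=` token; sequence lines are wrapped at 60
#' columns.
#'
#' @param genomes a [Genome-class] or list of them
#' @param path output file
#' @export
writeGenomeFasta <- function(genomes, path) {
  if (is(genomes, "Genome")) genomes <- list(genomes)
  set <- DNAStringSet(vapply(genomes, genomeString, character(1)))
  names(set) <- vapply(genomes, function(g)
    paste0(genomeId(g), " topology=", topology(g)), character(1))
  writeXStringSet(set, path, width = 60)
  invisible(path)
}

.attr1 <- function(x) if (is.null(x) || !length(x)) NA_character_ else as.character(x)[1]

#' Read a gene annotation from GFF3
#'
#' Expects `gene` rows carrying `ID`, `Name`, `category`, `origin`,
#' `trans_spliced` attributes and `exon` rows carrying `Parent` and an
#' optional integer `coding_order`. When `coding_order` is absent, exons are
#' ordered genomically (ascending on `+`, descending on `-`).
#'
#' @param path GFF3 file
#' @param genome the [Genome-class] the annotation refers to
#' @return an [AnnotationSet-class]
#' @export
readAnnotationGff <- function(path, genome) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  m <- mcols(gr)
  isGene <- m$type == "gene"
  isExon <- m$type == "exon"
  if (!any(isGene)) stop("no gene rows in '", path, "'")
  gg <- gr[isGene]; mg <- mcols(gg)
  genesDf <- data.frame(
    gene_id = as.character(mg$ID),
    name = ifelse(is.na(as.character(mg$Name)), as.character(mg$ID),
                  as.character(mg$Name)),
    category = as.character(mg$category),
    origin = ifelse(is.na(as.character(mg$origin)), "native",
                    as.character(mg$origin)),
    trans_spliced = !is.na(mg$trans_spliced) &
      tolower(as.character(mg$trans_spliced)) %in% c("true", "1", "yes"),
    stringsAsFactors = FALSE)
  if (anyDuplicated(genesDf$gene_id))
    stop("duplicate gene ID in '", path, "'")
  ee <- gr[isExon]; me <- mcols(ee)
  parent <- vapply(me$Parent, .attr1, character(1))
  if (any(is.na(parent))) stop("exon without Parent in '", path, "'")
  if (!all(parent %in% genesDf$gene_id))
    stop("exon Parent does not resolve to a gene in '", path, "'")
  co <- if (!is.null(me$coding_order))
    suppressWarnings(as.integer(as.character(me$coding_order)))
  else rep(NA_integer_, length(ee))
  ex <- GRanges(genomeId(genome),
                IRanges(start(ee), end(ee)), strand = strand(ee))
  mcols(ex)$gene_id <- parent
  mcols(ex)$coding_order <- co
  if (length(ex) && any(end(ex) > genomeLength(genome)))
    stop("exon outside genome in '", path, "'")
  ## fill missing coding_order genomically, per gene
  for (gid in unique(parent)) {
    idx <- which(mcols(ex)$gene_id == gid)
    if (any(is.na(mcols(ex)$coding_order[idx]))) {
      st <- as.character(strand(ex))[idx[1]]
      o <- order(start(ex)[idx], decreasing = (st == "-"))
      mcols(ex)$coding_order[idx[o]] <- seq_along(idx)
    }
  }
  AnnotationSet(genome, genesDf, ex)
}

#' Write a gene annotation as GFF3
#'
#' Emits the dialect read by [readAnnotationGff()].
#'
#' @param ann an [AnnotationSet-class]
#' @param path output file
#' @export
writeAnnotationGff <- function(ann, path) {
  g <- genes(ann)
  ex <- exons(ann)
  spans <- lapply(g$gene_id, function(gid) {
    e <- ex[mcols(ex)$gene_id == gid]
    c(min(start(e)), max(end(e)), as.character(strand(e))[1])
  })
  geneGr <- GRanges(ann@genomeId,
                    IRanges(vapply(spans, function(s) as.integer(s[1]), 1L),
                            vapply(spans, function(s) as.integer(s[2]), 1L)),
                    strand = vapply(spans, `[`, character(1), 3))
  mcols(geneGr)$type <- "gene"
  mcols(geneGr)$ID <- g$gene_id
  mcols(geneGr)$Name <- g$name
  mcols(geneGr)$category <- g$category
  mcols(geneGr)$origin <- g$origin
  mcols(geneGr)$trans_spliced <- ifelse(g$trans_spliced, "true", "false")
  mcols(geneGr)$Parent <- as(rep(list(character(0)), length(geneGr)),
                             "CharacterList")
  mcols(geneGr)$coding_order <- NA_character_
  exGr <- GRanges(ann@genomeId, IRanges(start(ex), end(ex)), strand = strand(ex))
  mcols(exGr)$type <- "exon"
  mcols(exGr)$ID <- NA_character_
  mcols(exGr)$Name <- NA_character_
  mcols(exGr)$category <- NA_character_
  mcols(exGr)$origin <- NA_character_
  mcols(exGr)$trans_spliced <- NA_character_
  mcols(exGr)$Parent <- as(as.character(mcols(ex)$gene_id), "CharacterList")
  mcols(exGr)$coding_order <- as.character(mcols(ex)$coding_order)
  mcols(exGr) <- mcols(exGr)[names(mcols(geneGr))]
  all <- c(geneGr, exGr)
  mcols(all)$source <- "mitoscan"
  rtracklayer::export(all, path, format = "gff3")
  invisible(path)
}
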