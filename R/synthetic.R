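## Deterministic toy-genome generator with planted ground truth for every
## downstream stage. All randomness flows from the seeds handed in (derived
## from PipelineConfig@rngSeed by the bundle wrapper); identical seeds give
## byte-identical output.

.BASES <- c("A", "C", "G", "T")

.randSeq <- function(n, gc = 0.48) {
  ## i.i.d. background with configurable GC bias (default echoes the high
  ## GC content typical of basal-eudicot mitochondrial genomes)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(.BASES, n, replace = TRUE, prob = p), collapse = "")
}

.SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                         c("TAA", "TAG", "TGA"))
.STOP_CODONS <- c("TAA", "TAG", "TGA")

.containsSsr <- function(seq, min_units = c(10L, 5L, 4L, 3L, 3L, 3L))
  nrow(findSsrs(seq, min_units)) > 0L

## random CDS: ATG start, single stop at the end, no internal stops,
## screened against SSR-threshold runs so planted-SSR truth stays unambiguous
.randCds <- function(len, gc = 0.48) {
  stopifnot(len %% 3L == 0L, len >= 9L)
  for (try in 1:25) {
    body <- sample(.SENSE_CODONS, len %/% 3L - 2L, replace = TRUE)
    cds <- paste0("ATG", paste(body, collapse = ""),
                  sample(.STOP_CODONS, 1L))
    if (!.containsSsr(cds)) return(cds)
  }
  stop("could not generate an SSR-free CDS of length ", len)
}

.randNonCoding <- function(len, gc = 0.48) {
  for (try in 1:25) {
    s <- .randSeq(len, gc)
    if (!.containsSsr(s)) return(s)
  }
  stop("could not generate an SSR-free segment of length ", len)
}

.writeSeg <- function(ch, start, seg) {
  ch[start:(start + nchar(seg) - 1L)] <- strsplit(seg, "")[[1]]
  ch
}

.protCatalog <- c(atp9 = 225L, ccmB = 621L, cox1 = 786L, cox2 = 510L,
                  atp6 = 660L, rps3 = 450L, rpl16 = 390L, matR = 900L,
                  nad3 = 360L, ccmC = 570L, sdh4 = 300L, rps12 = 378L)

#' Generate a synthetic mitochondrial genome with annotated genes
#'
#' Emits a circular genome carrying a mix of forward- and reverse-strand
#' genes that exercises every downstream stage: a two-exon cis-spliced
#' gene, a trans-spliced gene split across two distant loci, a pair of
#' identical duplicated genes (`-1`/`-2` naming), a reading-frame-less
#' pseudogene, an rRNA, a native and a plastid-derived tRNA, and
#' single-exon protein genes drawn from a catalog of realistic organelle
#' gene lengths. Protein CDSs start with ATG, end with a single stop and
#' contain no internal stops. Identical seeds give identical output.
#'
#' @param config a [PipelineConfig-class]; `rngSeed` drives all randomness
#' @param n_genes number of gene models (>= 4)
#' @param genome_len genome length, bp (must fit the requested genes)
#' @return list: `genome` ([Genome-class]), `ann` ([AnnotationSet-class]),
#'   `truth` (list with `gene_cds`, `rng_seed`)
#' @export
generateMtGenome <- function(config = PipelineConfig(), n_genes = 12L,
                             genome_len = 30000L) {
  if (n_genes < 4L) stop("n_genes must be >= 4 (cis, trans and a duplicated pair)")
  set.seed(config@rngSeed)
  gc <- 0.48

  specials <- list(
    list(id = "nad7", name = "nad7", category = "protein", origin = "native",
         trans = FALSE, cds_len = 480L, exon_w = c(240L, 240L), intron = NA),
    list(id = "nad1", name = "nad1", category = "protein", origin = "native",
         trans = TRUE, cds_len = 600L, exon_w = c(300L, 300L), intron = NA),
    list(id = "rps19-1", name = "rps19-1", category = "protein",
         origin = "native", trans = FALSE, cds_len = 279L, exon_w = 279L),
    list(id = "rps19-2", name = "rps19-2", category = "protein",
         origin = "native", trans = FALSE, cds_len = 279L, exon_w = 279L),
    list(id = "mttB", name = "mttB", category = "pseudogene",
         origin = "native", trans = FALSE, cds_len = 400L, exon_w = 400L),
    list(id = "rrn18", name = "rrn18", category = "rRNA", origin = "native",
         trans = FALSE, cds_len = 900L, exon_w = 900L),
    list(id = "trnE", name = "trnE(TTC)", category = "tRNA",
         origin = "native", trans = FALSE, cds_len = 72L, exon_w = 72L),
    list(id = "trnN-cp", name = "trnN(GTT)-cp", category = "tRNA",
         origin = "plastid_derived", trans = FALSE, cds_len = 72L,
         exon_w = 72L))
  plan <- specials[seq_len(min(n_genes, length(specials)))]
  extra <- n_genes - length(plan)
  if (extra > 0L) {
    if (extra > length(.protCatalog))
      stop("infeasible packing: catalog exhausted, at most ",
           length(specials) + length(.protCatalog), " genes supported")
    for (i in seq_len(extra)) {
      nm <- names(.protCatalog)[i]
      plan[[length(plan) + 1L]] <- list(
        id = nm, name = nm, category = "protein", origin = "native",
        trans = FALSE, cds_len = .protCatalog[[i]],
        exon_w = .protCatalog[[i]])
    }
  }

  need <- sum(vapply(plan, function(p) sum(p$exon_w), integer(1))) +
    length(plan) * 450L + 600L
  if (genome_len < need)
    stop("infeasible packing: ", genome_len, " bp cannot hold ", n_genes,
         " genes (need about ", need, " bp including spacers)")

  ## sequences per gene
  seqs <- lapply(plan, function(p) {
    if (p$category == "protein") .randCds(p$cds_len, gc)
    else .randNonCoding(p$cds_len, gc)
  })
  ## identical duplicated pair
  i1 <- which(vapply(plan, function(p) p$id == "rps19-1", logical(1)))
  i2 <- which(vapply(plan, function(p) p$id == "rps19-2", logical(1)))
  if (length(i1) && length(i2)) seqs[[i2]] <- seqs[[i1]]

  ## placement units: one per gene, except trans genes contribute two
  ## groups placed apart; exon widths listed in coding order
  units <- list()
  for (i in seq_along(plan)) {
    p <- plan[[i]]
    strand <- sample(c("+", "-"), 1L)
    if (isTRUE(p$trans)) {
      s2 <- sample(c("+", "-"), 1L)
      units[[length(units) + 1L]] <- list(gene = i, widths = p$exon_w[1],
                                          coding = 1L, strand = strand,
                                          cds_off = 0L)
      units[[length(units) + 1L]] <- list(gene = i, widths = p$exon_w[2],
                                          coding = 2L, strand = s2,
                                          cds_off = p$exon_w[1])
    } else if (length(p$exon_w) > 1L) {
      units[[length(units) + 1L]] <- list(gene = i, widths = p$exon_w,
                                          coding = seq_along(p$exon_w),
                                          strand = strand, cds_off = 0L,
                                          intron = sample(80:200, length(p$exon_w) - 1L,
                                                          replace = TRUE))
    } else {
      units[[length(units) + 1L]] <- list(gene = i, widths = p$exon_w,
                                          coding = 1L, strand = strand,
                                          cds_off = 0L)
    }
  }
  ## separate the two groups of each trans gene in the placement order
  ord <- seq_along(units)
  transSecond <- which(vapply(units, function(u)
    length(u$coding) == 1L && u$coding == 2L, logical(1)))
  if (length(transSecond)) {
    rest <- setdiff(ord, transSecond)
    ord <- c(rest, transSecond)   # second group lands far downstream
  }

  ch <- strsplit(.randSeq(genome_len, gc), "")[[1]]
  exRows <- list()
  cursor <- sample(200:400, 1L)
  for (ui in ord) {
    u <- units[[ui]]
    p <- plan[[u$gene]]
    cds <- seqs[[u$gene]]
    widths <- u$widths
    ## genomic order of this unit's exons: coding order on +, reversed on -
    genomicIdx <- if (u$strand == "-") rev(seq_along(widths)) else seq_along(widths)
    offs <- u$cds_off + c(0L, cumsum(widths))[seq_along(widths)]
    starts <- integer(length(widths))
    pos <- cursor
    for (gi in seq_along(genomicIdx)) {
      k <- genomicIdx[gi]
      starts[k] <- pos
      pos <- pos + widths[k]
      if (gi < length(genomicIdx)) pos <- pos + u$intron[gi]
    }
    if (pos > genome_len - 450L)
      stop("infeasible packing: ran out of genome at ", pos, " bp")
    for (k in seq_along(widths)) {
      part <- substr(cds, offs[k] + 1L, offs[k] + widths[k])
      seg <- if (u$strand == "-") .revcompChr(part) else part
      ch <- .writeSeg(ch, starts[k], seg)
      exRows[[length(exRows) + 1L]] <- data.frame(
        gene_id = p$id, start = starts[k], end = starts[k] + widths[k] - 1L,
        strand = u$strand, coding_order = u$coding[k],
        stringsAsFactors = FALSE)
    }
    cursor <- pos + sample(150:400, 1L)
  }

  genesDf <- do.call(rbind, lapply(plan, function(p)
    data.frame(gene_id = p$id, name = p$name, category = p$category,
               origin = p$origin, trans_spliced = isTRUE(p$trans),
               stringsAsFactors = FALSE)))
  exDf <- do.call(rbind, exRows)
  genome <- Genome("mt_synth", paste(ch, collapse = ""), topology = "circular")
  ex <- GRanges("mt_synth", IRanges(exDf$start, exDf$end), strand = exDf$strand)
  mcols(ex)$gene_id <- exDf$gene_id
  mcols(ex)$coding_order <- exDf$coding_order
  ann <- AnnotationSet(genome, genesDf, ex)
  truth <- list(gene_cds = stats::setNames(unlist(seqs),
                                           vapply(plan, `[[`, "", "id")),
                rng_seed = config@rngSeed)
  list(genome = genome, ann = ann, truth = truth)
}

#' Generate a synthetic chloroplast genome
#'
#' A circular genome with a handful of single-exon genes (two protein, two
#' tRNA) used as the source molecule for planted chloroplast-derived
#' fragments. The background is screened so no SSR-threshold run can be
#' copied into the mitochondrial genome by fragment planting.
#'
#' @param seed integer seed
#' @param genome_len genome length, bp
#' @return list: `genome`, `ann`
#' @export
generateCpGenome <- function(seed = 2L, genome_len = 12000L) {
  set.seed(seed)
  plan <- list(
    list(id = "psbM", name = "psbM", category = "protein", len = 270L),
    list(id = "ycf2", name = "ycf2", category = "protein", len = 570L),
    list(id = "trnH-cp", name = "trnH(GTG)", category = "tRNA", len = 74L),
    list(id = "trnN-src", name = "trnN(GTT)", category = "tRNA", len = 72L))
  ch <- strsplit(.randSeq(genome_len, 0.38), "")[[1]]
  cursor <- 500L
  exRows <- list()
  seqs <- list()
  for (p in plan) {
    s <- if (p$category == "protein") .randCds(p$len) else .randNonCoding(p$len)
    seqs[[p$id]] <- s
    ch <- .writeSeg(ch, cursor, s)
    exRows[[length(exRows) + 1L]] <- data.frame(
      gene_id = p$id, start = cursor, end = cursor + p$len - 1L,
      strand = "+", coding_order = 1L, stringsAsFactors = FALSE)
    cursor <- cursor + p$len + sample(800:1500, 1L)
  }
  ## sanitize chance SSR runs in the background so fragment planting
  ## cannot copy an unplanted SSR into the mitochondrial genome
  g <- Genome("cp_synth", paste(ch, collapse = ""), topology = "circular")
  exDf <- do.call(rbind, exRows)
  protect <- IRanges(exDf$start, exDf$end)
  g <- .sanitizeSsrs(g, protect)
  ex <- GRanges("cp_synth", IRanges(exDf$start, exDf$end), strand = exDf$strand)
  mcols(ex)$gene_id <- exDf$gene_id
  mcols(ex)$coding_order <- exDf$coding_order
  genesDf <- do.call(rbind, lapply(plan, function(p)
    data.frame(gene_id = p$id, name = p$name, category = p$category,
               origin = "native", trans_spliced = FALSE,
               stringsAsFactors = FALSE)))
  list(genome = g, ann = AnnotationSet(g, genesDf, ex))
}

## mutate one background base inside each chance SSR run (outside protected
## ranges) until the genome carries no unplanted SSR-threshold run
.sanitizeSsrs <- function(genome, protect, min_units = c(10L, 5L, 4L, 3L, 3L, 3L),
                          passes = 6L) {
  for (pass in seq_len(passes)) {
    ssrs <- findSsrs(genome, min_units)
    if (!nrow(ssrs)) return(genome)
    n <- genomeLength(genome)
    todo <- seq_len(nrow(ssrs))
    hit <- FALSE
    ch <- strsplit(genomeString(genome), "")[[1]]
    for (i in todo) {
      posRange <- ssrs$start[i]:min(ssrs$end[i], n)
      free <- posRange[IRanges::countOverlaps(IRanges(posRange, posRange),
                                              protect) == 0L]
      if (!length(free)) next
      p <- free[ceiling(length(free) / 2)]
      cur <- ch[p]
      repl <- setdiff(.BASES, c(cur, ch[max(1L, p - 1L)],
                                ch[min(n, p + 1L)]))
      if (!length(repl)) repl <- setdiff(.BASES, cur)
      ch[p] <- repl[1]
      hit <- TRUE
    }
    if (!hit) break
    genome <- Genome(genomeId(genome), paste(ch, collapse = ""),
                     topology = topology(genome))
  }
  genome
}

.freeSlots <- function(genome_len, occupied, margin = 30L) {
  occ <- IRanges::reduce(occupied)
  gaps <- IRanges::gaps(occ, start = 1L, end = genome_len)
  gaps[IRanges::width(gaps) > 2L * margin]
}

.mutateSeq <- function(seg, rate) {
  if (rate <= 0) return(seg)
  ch <- strsplit(seg, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (p in hit) ch[p] <- sample(setdiff(.BASES, ch[p]), 1L)
  paste(ch, collapse = "")
}

#' Plant chloroplast-derived fragments into a mitochondrial genome
#'
#' Copies segments of the chloroplast genome into intergenic regions of the
#' mitochondrial genome (overwriting background, so coordinates of existing
#' features are unchanged), on either strand, with an optional per-base
#' substitution rate. Flanking bases are guarded so that a local alignment
#' cannot extend past the planted boundary, keeping the recorded truth
#' exact.
#'
#' @param mt mitochondrial [Genome-class]
#' @param mt_ann its [AnnotationSet-class] (placement avoids gene exons)
#' @param cp chloroplast [Genome-class]
#' @param lengths fragment lengths, bp
#' @param divergence per-base substitution rate applied to each copy
#' @param seed integer seed
#' @param occupied optional extra [IRanges::IRanges] to avoid on mt
#' @param cp_starts optional fixed chloroplast start per fragment (NA =
#'   random); used e.g. to make a fragment contain a chloroplast gene
#' @return list: `genome` (modified mt), `truth` (data.frame mt_start,
#'   mt_end, cp_start, cp_end, strand, length, divergence)
#' @export
plantCpFragments <- function(mt, mt_ann, cp, lengths = c(1000L, 500L, 300L,
                                                         120L, 54L),
                             divergence = 0, seed = 3L, occupied = NULL,
                             cp_starts = NULL) {
  set.seed(seed)
  n <- genomeLength(mt)
  cpLen <- genomeLength(cp)
  occ <- IRanges::ranges(exons(mt_ann))
  if (!is.null(occupied)) occ <- c(occ, occupied)
  free <- .freeSlots(n, occ)
  ch <- strsplit(genomeString(mt), "")[[1]]
  cpch <- strsplit(genomeString(cp), "")[[1]]
  usedCp <- IRanges()
  if (is.null(cp_starts)) cp_starts <- rep(NA_integer_, length(lengths))
  rows <- list()
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  for (i in order(-lengths)) {
    L <- lengths[i]
    ## chloroplast source interval, disjoint from earlier sources
    cs <- cp_starts[i]
    for (try in 1:50) {
      if (is.na(cs)) cs <- sample(2:(cpLen - L), 1L)
      cand <- IRanges(cs, cs + L - 1L)
      if (!length(IRanges::findOverlaps(cand, usedCp))) break
      cs <- NA_integer_
      if (try == 50L) stop("no disjoint chloroplast source interval of ", L, " bp")
    }
    ce <- cs + L - 1L
    usedCp <- c(usedCp, IRanges(cs, ce))
    ## mitochondrial slot
    wide <- free[IRanges::width(free) >= L + 62L]
    if (!length(wide))
      stop("no intergenic space for a ", L, "-bp fragment")
    slot <- wide[sample(length(wide), 1L)]
    ms <- IRanges::start(slot) + 31L
    me <- ms + L - 1L
    strand <- sample(c("+", "-"), 1L)
    seg <- substr(genomeString(cp), cs, ce)
    seg <- .mutateSeq(seg, divergence)
    if (strand == "-") seg <- .revcompChr(seg)
    ch <- .writeSeg(ch, ms, seg)
    ## boundary guards: several bases just outside the copy must not
    ## continue the alignment in either orientation, so a local alignment
    ## cannot creep past the planted boundary on chance matches
    guard <- function(p, avoid) {
      if (p < 1L || p > n) return()
      if (ch[p] == avoid)
        ch[p] <<- setdiff(.BASES, c(avoid, ch[p]))[1]
    }
    for (o in 1:4) {
      if (strand == "+") {
        if (cs - o >= 1L) guard(ms - o, cpch[cs - o])
        if (ce + o <= cpLen) guard(me + o, cpch[ce + o])
      } else {
        if (ce + o <= cpLen) guard(ms - o, comp[[cpch[ce + o]]])
        if (cs - o >= 1L) guard(me + o, comp[[cpch[cs - o]]])
      }
    }
    ## remove the used slot from the free list
    occ <- c(occ, IRanges(ms - 31L, me + 31L))
    free <- .freeSlots(n, occ)
    rows[[length(rows) + 1L]] <- data.frame(
      mt_start = ms, mt_end = me, cp_start = cs, cp_end = ce,
      strand = strand, length = L, divergence = divergence,
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, rows)
  truth <- truth[order(-truth$length), , drop = FALSE]
  rownames(truth) <- NULL
  list(genome = Genome(genomeId(mt), paste(ch, collapse = ""),
                       topology = topology(mt)),
       truth = truth)
}

#' Plant long repeats and SSR loci
#'
#' Direct repeats are two identical copies of a screened random segment;
#' inverted repeats place the reverse complement as the second copy. SSRs
#' are written verbatim as `motif` repeated `n_units` times. All planted
#' loci avoid gene exons, previously planted features and each other, and
#' flanking bases are guarded so each planted feature is maximal exactly at
#' its recorded boundary.
#'
#' @param genome a [Genome-class]
#' @param ann its [AnnotationSet-class]
#' @param repeat_spec data.frame with columns `kind` (direct/inverted) and
#'   `length` (>= 20 bp)
#' @param ssr_spec data.frame with columns `motif` (primitive, 1-6 nt) and
#'   `n_units`
#' @param seed integer seed
#' @param occupied optional extra [IRanges::IRanges] to avoid
#' @return list: `genome`, `truth` (list with `repeats` and `ssrs`
#'   data.frames)
#' @export
plantRepeatsAndSsrs <- function(genome, ann,
                                repeat_spec = data.frame(
                                  kind = c("direct", "direct", "inverted",
                                           "inverted"),
                                  length = c(600L, 550L, 700L, 520L)),
                                ssr_spec = data.frame(
                                  motif = c("A", "AT", "AGC", "AATG",
                                            "AACGT", "AACGTC"),
                                  n_units = c(12L, 6L, 5L, 4L, 3L, 3L)),
                                seed = 4L, occupied = NULL) {
  stopifnot(all(repeat_spec$length >= 20L))
  stopifnot(all(nchar(ssr_spec$motif) %in% 1:6),
            all(vapply(as.character(ssr_spec$motif), .isPrimitive, logical(1))))
  set.seed(seed)
  n <- genomeLength(genome)
  occ <- IRanges::ranges(exons(ann))
  if (!is.null(occupied)) occ <- c(occ, occupied)
  ch <- strsplit(genomeString(genome), "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  claim <- function(L) {
    free <- .freeSlots(n, occ, margin = 35L)
    wide <- free[IRanges::width(free) >= L + 72L]
    if (!length(wide)) stop("no space left for a ", L, "-bp planted feature")
    slot <- wide[sample(length(wide), 1L)]
    s <- IRanges::start(slot) + 36L
    occ <<- c(occ, IRanges(s - 36L, s + L + 35L))
    s
  }
  setBase <- function(p, avoid) {
    if (p < 1L || p > n) return()
    if (ch[p] %in% avoid)
      ch[p] <<- setdiff(.BASES, avoid)[1]
  }
  repRows <- list()
  if (nrow(repeat_spec)) for (i in seq_len(nrow(repeat_spec))) {
    L <- repeat_spec$length[i]
    kind <- as.character(repeat_spec$kind[i])
    seg <- .randNonCoding(L)
    a <- claim(L); b <- claim(L)
    if (b < a) { tmp <- a; a <- b; b <- tmp }
    segB <- if (kind == "inverted") .revcompChr(seg) else seg
    ch <- .writeSeg(ch, a, seg)
    ch <- .writeSeg(ch, b, segB)
    a2 <- a + L - 1L; b2 <- b + L - 1L
    for (o in 1:3) {
      if (kind == "direct") {
        setBase(b - o, ch[a - o])
        setBase(b2 + o, ch[a2 + o])
      } else {
        setBase(b2 + o, comp[[ch[a - o]]])
        setBase(b - o, comp[[ch[a2 + o]]])
      }
    }
    repRows[[length(repRows) + 1L]] <- data.frame(
      kind = kind, start_a = a, end_a = a2, start_b = b, end_b = b2,
      length = L, stringsAsFactors = FALSE)
  }
  ssrRows <- list()
  if (nrow(ssr_spec)) for (i in seq_len(nrow(ssr_spec))) {
    motif <- toupper(as.character(ssr_spec$motif[i]))
    nu <- ssr_spec$n_units[i]
    L <- nchar(motif) * nu
    s <- claim(L)
    ch <- .writeSeg(ch, s, strrep(motif, nu))
    k <- nchar(motif)
    setBase(s - 1L, substr(motif, k, k))     # no left extension of the run
    setBase(s + L, substr(motif, 1L, 1L))    # no right extension
    ssrRows[[length(ssrRows) + 1L]] <- data.frame(
      motif = motif, n_units = nu, start = s, end = s + L - 1L,
      stringsAsFactors = FALSE)
  }
  list(genome = Genome(genomeId(genome), paste(ch, collapse = ""),
                       topology = topology(genome)),
       truth = list(repeats = if (length(repRows)) do.call(rbind, repRows)
                      else NULL,
                    ssrs = if (length(ssrRows)) do.call(rbind, ssrRows)
                      else NULL))
}

#' Sample a planted-edit truth set
#'
#' Draws editable positions across protein-coding genes and the pseudogene:
#' C positions for C-to-U edits (the dominant direction in plant
#' mitochondria) and T positions for the rare U-to-C direction.
#'
#' @param cds_seqs named character vector of spliced CDSs (the genes to
#'   edit)
#' @param n_edits total number of edits
#' @param n_u2c how many of them are U-to-C
#' @param seed integer seed
#' @return data.frame: gene_id, cds_pos, direction
#' @export
sampleEditTruth <- function(cds_seqs, n_edits = 40L, n_u2c = 2L, seed = 5L) {
  set.seed(seed)
  stopifnot(n_u2c <= n_edits)
  pool <- do.call(rbind, lapply(names(cds_seqs), function(g) {
    ch <- strsplit(cds_seqs[[g]], "")[[1]]
    data.frame(gene_id = g, cds_pos = seq_along(ch), base = ch,
               stringsAsFactors = FALSE)
  }))
  cPool <- pool[pool$base == "C", ]
  tPool <- pool[pool$base == "T", ]
  if (nrow(cPool) < n_edits - n_u2c || nrow(tPool) < n_u2c)
    stop("not enough editable positions")
  pick <- rbind(
    cbind(cPool[sample(nrow(cPool), n_edits - n_u2c), c("gene_id", "cds_pos")],
          direction = "C2U"),
    cbind(tPool[sample(nrow(tPool), n_u2c), c("gene_id", "cds_pos")],
          direction = "U2C"))
  pick <- pick[order(pick$gene_id, pick$cds_pos), ]
  rownames(pick) <- NULL
  pick
}

#' Generate cDNA sequences with planted edits and optional noise
#'
#' The cDNA of each gene is its spliced CDS with the planted substitutions
#' applied in cDNA space (C->T for C-to-U edits, T->C for U-to-C), plus
#' optional uniform substitution noise for robustness testing. An edit at a
#' position whose base cannot be edited in the stated direction is an
#' error.
#'
#' @param genome a [Genome-class]
#' @param ann an [AnnotationSet-class]
#' @param truth_edits data.frame gene_id/cds_pos/direction (e.g. from
#'   [sampleEditTruth()])
#' @param noise_rate per-base substitution noise on the cDNA
#' @param seed integer seed (noise only)
#' @return list: `cdna` (named character), `noise` (data.frame gene_id,
#'   cds_pos, from, to)
#' @export
generateCdna <- function(genome, ann, truth_edits = NULL, noise_rate = 0,
                         seed = 6L) {
  set.seed(seed)
  g <- genes(ann)
  ids <- g$gene_id[g$category %in% c("protein", "pseudogene")]
  cdna <- vapply(ids, function(gid) spliceCds(genome, ann, gid), character(1))
  names(cdna) <- ids
  if (!is.null(truth_edits) && nrow(truth_edits)) {
    for (i in seq_len(nrow(truth_edits))) {
      gid <- truth_edits$gene_id[i]
      p <- truth_edits$cds_pos[i]
      dir <- truth_edits$direction[i]
      base <- substr(cdna[[gid]], p, p)
      need <- if (dir == "C2U") "C" else "T"
      if (base != need)
        stop(sprintf("edit %s:%d wants %s but CDS has %s", gid, p, need, base))
      substr(cdna[[gid]], p, p) <- if (dir == "C2U") "T" else "C"
    }
  }
  noise <- data.frame(gene_id = character(), cds_pos = integer(),
                      from = character(), to = character(),
                      stringsAsFactors = FALSE)
  if (noise_rate > 0) {
    for (gid in ids) {
      ch <- strsplit(cdna[[gid]], "")[[1]]
      hit <- which(stats::runif(length(ch)) < noise_rate)
      for (p in hit) {
        to <- sample(setdiff(.BASES, ch[p]), 1L)
        noise <- rbind(noise, data.frame(gene_id = gid, cds_pos = p,
                                         from = ch[p], to = to))
        ch[p] <- to
      }
      cdna[[gid]] <- paste(ch, collapse = "")
    }
  }
  list(cdna = cdna, noise = noise)
}

#' Simulate a complete analysis bundle with planted ground truth
#'
#' Chains the generators: a chloroplast genome, a mitochondrial genome with
#' annotated genes, planted chloroplast-derived fragments (the first one
#' containing an intact chloroplast tRNA gene), planted long repeats and
#' SSR loci, a background sanitization pass that removes chance
#' SSR-threshold runs so planted truth is unambiguous, planted RNA edits
#' and the corresponding cDNA set. Everything is reproducible from
#' `config@rngSeed` (stage seeds are derived by fixed offsets).
#'
#' @param config a [PipelineConfig-class]
#' @param n_genes,mt_len,cp_len genome composition parameters
#' @param n_edits,n_u2c planted edit counts
#' @param fragment_lengths planted chloroplast fragment lengths, bp
#' @param repeat_spec,ssr_spec see [plantRepeatsAndSsrs()]
#' @param noise_rate cDNA substitution noise
#' @param divergence fragment substitution divergence
#' @return list: `mt`, `mt_ann`, `cp`, `cp_ann`, `cdna`, `truth` (list:
#'   `edits`, `fragments`, `repeats`, `ssrs`, `gene_cds`, `noise`,
#'   `rng_seed`), `config`
#' @export
simulateBundle <- function(config = PipelineConfig(), n_genes = 12L,
                           mt_len = 30000L, cp_len = 12000L, n_edits = 40L,
                           n_u2c = 2L,
                           fragment_lengths = c(1000L, 500L, 300L, 120L, 54L),
                           repeat_spec = NULL, ssr_spec = NULL,
                           noise_rate = 0, divergence = 0) {
  base <- config@rngSeed
  cpb <- generateCpGenome(seed = base + 101L, genome_len = cp_len)
  mtb <- generateMtGenome(config, n_genes = n_genes, genome_len = mt_len)
  ## the largest fragment is pinned to contain the chloroplast trnN gene
  cpStarts <- rep(NA_integer_, length(fragment_lengths))
  if (length(fragment_lengths)) {
    tr <- exons(cpb$ann)[mcols(exons(cpb$ann))$gene_id == "trnN-src"]
    if (length(tr) && fragment_lengths[1] >= width(tr) + 20L)
      cpStarts[1] <- max(1L, start(tr) - 10L)
  }
  fr <- plantCpFragments(mtb$genome, mtb$ann, cpb$genome,
                         lengths = fragment_lengths, divergence = divergence,
                         seed = base + 102L, cp_starts = cpStarts)
  fragOcc <- IRanges(fr$truth$mt_start, fr$truth$mt_end)
  defaults <- is.null(repeat_spec) && is.null(ssr_spec)
  if (is.null(repeat_spec))
    repeat_spec <- data.frame(kind = c("direct", "direct", "inverted",
                                       "inverted"),
                              length = c(600L, 550L, 700L, 520L))
  if (is.null(ssr_spec))
    ssr_spec <- data.frame(motif = c("A", "AT", "AGC", "AATG", "AACGT",
                                     "AACGTC"),
                           n_units = c(12L, 6L, 5L, 4L, 3L, 3L))
  rs <- plantRepeatsAndSsrs(fr$genome, mtb$ann, repeat_spec, ssr_spec,
                            seed = base + 103L, occupied = fragOcc)
  ## sanitize chance SSRs everywhere outside planted/annotated features
  protect <- c(IRanges::ranges(exons(mtb$ann)), fragOcc,
               IRanges(rs$truth$repeats$start_a, rs$truth$repeats$end_a),
               IRanges(rs$truth$repeats$start_b, rs$truth$repeats$end_b),
               IRanges(rs$truth$ssrs$start, rs$truth$ssrs$end))
  mt <- .sanitizeSsrs(rs$genome, protect)
  editable <- mtb$truth$gene_cds[
    genes(mtb$ann)$gene_id[genes(mtb$ann)$category %in%
                             c("protein", "pseudogene")]]
  ## identical duplicated copies carry identical edits in vivo: sample on
  ## one representative per identical-CDS group, then mirror onto the rest
  rep_ids <- names(editable)[!duplicated(unname(editable))]
  edits <- sampleEditTruth(editable[rep_ids], n_edits = n_edits,
                           n_u2c = n_u2c, seed = base + 104L)
  mirrored <- edits
  for (gid in setdiff(names(editable), rep_ids)) {
    twin <- rep_ids[match(editable[[gid]], unname(editable[rep_ids]))]
    extra <- edits[edits$gene_id == twin, , drop = FALSE]
    if (nrow(extra)) {
      extra$gene_id <- gid
      mirrored <- rbind(mirrored, extra)
    }
  }
  cd <- generateCdna(mt, mtb$ann, mirrored, noise_rate = noise_rate,
                     seed = base + 105L)
  ## re-anchor the annotation on the final (sanitized) genome object
  ann <- AnnotationSet(mt, genes(mtb$ann), exons(mtb$ann))
  list(mt = mt, mt_ann = ann, cp = cpb$genome, cp_ann = cpb$ann,
       cdna = cd$cdna,
       truth = list(edits = edits, edits_all_copies = mirrored,
                    fragments = fr$truth,
                    repeats = rs$truth$repeats, ssrs = rs$truth$ssrs,
                    gene_cds = mtb$truth$gene_cds, noise = cd$noise,
                    rng_seed = base),
       config = config)
}

#' Write a simulated bundle to a directory
#'
#' Emits the FASTA/GFF3 dialects plus a structured `truth.json` sidecar for
#' test harnesses: `mt.fasta`, `mt.gff3`, `cp.fasta`, `cp.gff3`,
#' `cdna.fasta` (records keyed by gene_id) and `truth.json`.
#'
#' @param bundle list from [simulateBundle()]
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
writeBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeGenomeFasta(bundle$mt, file.path(dir, "mt.fasta"))
  writeGenomeFasta(bundle$cp, file.path(dir, "cp.fasta"))
  writeAnnotationGff(bundle$mt_ann, file.path(dir, "mt.gff3"))
  writeAnnotationGff(bundle$cp_ann, file.path(dir, "cp.gff3"))
  set <- DNAStringSet(unname(bundle$cdna))
  names(set) <- names(bundle$cdna)
  writeXStringSet(set, file.path(dir, "cdna.fasta"), width = 60)
  truth <- bundle$truth
  truth$gene_cds <- as.list(truth$gene_cds)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a cDNA FASTA keyed by gene id
#' @param path FASTA file whose record names are gene_ids
#' @return named character vector
#' @export
readCdnaFasta <- function(path) {
  set <- readDNAStringSet(path)
  out <- toupper(as.character(set))
  names(out) <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  out
}
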