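#' @importFrom Biostrings pairwiseAlignment nmatch
NULL

## Local-alignment scoring used by the in-package BLAST-like search:
## match +1, mismatch -2, gap of length L costs 5 + 2L. The e-value uses
## fixed documented Karlin-Altschul-style constants K = 0.41, lambda = 1.28
## (ungapped nucleotide approximations); identity and coverage floors, not
## the e-value, are the scientifically decisive filters.
.LOCAL_SUB <- local({
  m <- matrix(-2, 5, 5, dimnames = list(c("A","C","G","T","N"),
                                        c("A","C","G","T","N")))
  diag(m) <- 1
  m["N", ] <- -2; m[, "N"] <- -2
  m
})
.KA_K <- 0.41
.KA_LAMBDA <- 1.28

.evalue <- function(score, m, n) .KA_K * m * n * exp(-.KA_LAMBDA * score)

.emptyHits <- function()
  data.frame(q_start = integer(), q_end = integer(), s_start = integer(),
             s_end = integer(), strand = character(), matches = integer(),
             aln_length = integer(), identity = numeric(), score = numeric(),
             evalue = numeric(), stringsAsFactors = FALSE)

## Run one local alignment between query window [qa,qb] and subject window
## [sa,sb] (subject given on the searched strand); report in original
## coordinates. qlen/slen are full lengths for the e-value.
.refineHit <- function(qseq, sseq, qa, qb, sa, sb, strand, qlen, slen) {
  pa <- pairwiseAlignment(substr(qseq, qa, qb), substr(sseq, sa, sb),
                          type = "local", substitutionMatrix = .LOCAL_SUB,
                          gapOpening = 5, gapExtension = 2)
  sc <- Biostrings::score(pa)
  if (sc <= 0) return(NULL)
  ap <- as.character(Biostrings::alignedPattern(pa))
  alnLen <- nchar(ap)
  qs <- qa + Biostrings::start(Biostrings::pattern(pa)) - 1L
  qe <- qa + Biostrings::end(Biostrings::pattern(pa)) - 1L
  ss <- sa + Biostrings::start(Biostrings::subject(pa)) - 1L
  se <- sa + Biostrings::end(Biostrings::subject(pa)) - 1L
  if (strand == "-") {            # map back from reverse-complement coords
    tmp <- slen - se + 1L
    se <- slen - ss + 1L
    ss <- tmp
  }
  data.frame(q_start = qs, q_end = qe, s_start = ss, s_end = se,
             strand = strand, matches = nmatch(pa), aln_length = alnLen,
             identity = nmatch(pa) / alnLen, score = sc,
             evalue = .evalue(sc, qlen, slen), stringsAsFactors = FALSE)
}

.seedWindows <- function(qseq, sseq, k, seed_gap) {
  nq <- nchar(qseq); ns <- nchar(sseq)
  if (nq < k || ns < k) return(NULL)
  qpos <- 1:(nq - k + 1L)
  qkm <- substring(qseq, qpos, qpos + k - 1L)
  okq <- !grepl("N", qkm, fixed = TRUE)
  idx <- split(qpos[okq], qkm[okq])
  idx <- idx[lengths(idx) <= 50L]
  spos <- 1:(ns - k + 1L)
  skm <- substring(sseq, spos, spos + k - 1L)
  oks <- !grepl("N", skm, fixed = TRUE)
  sidx <- split(spos[oks], skm[oks])
  sidx <- sidx[lengths(sidx) <= 50L]
  common <- intersect(names(idx), names(sidx))
  pi <- integer(); pj <- integer()
  for (km in common) {
    grid <- expand.grid(i = idx[[km]], j = sidx[[km]])
    pi <- c(pi, grid$i); pj <- c(pj, grid$j)
  }
  if (!length(pi)) return(NULL)
  d <- pj - pi
  wins <- list()
  for (dg in unique(d)) {
    ii <- sort(pi[d == dg])
    br <- c(0L, which(diff(ii) > seed_gap), length(ii))
    for (ci in seq_len(length(br) - 1L)) {
      grp <- ii[(br[ci] + 1L):br[ci + 1L]]
      wins[[length(wins) + 1L]] <- c(qa = grp[1], qb = grp[length(grp)] + k - 1L,
                                     dg = dg)
    }
  }
  wins
}

#' BLAST-like local similarity search
#'
#' Finds local alignments of the query against both strands of the subject
#' with identity at or above `min_identity` and e-value at or below
#' `max_evalue`. Scoring is +1 match, -2 mismatch, gap open -5 and gap
#' extend -2; the e-value is `K * m * n * exp(-lambda * score)` with the
#' documented constants K = 0.41, lambda = 1.28. Candidate regions come
#' from exact k-mer seeds (N-masked regions never seed hits) merged on
#' diagonals; each candidate window is refined by an exact local
#' (Smith-Waterman) alignment. Small inputs skip seeding and are aligned
#' exactly. Overlapping hits are collapsed to the highest-scoring.
#'
#' @param query,subject character sequences (A/C/G/T/N)
#' @param min_identity identity floor, fraction
#' @param max_evalue e-value ceiling
#' @param k seed length for large inputs
#' @param seed_gap diagonal seed-merge distance, bp
#' @param pad window padding before refinement, bp
#' @return data.frame of hits: q_start, q_end, s_start, s_end (subject
#'   forward-strand coordinates), strand, matches, aln_length, identity,
#'   score, evalue
#' @export
localSearch <- function(query, subject, min_identity = 0.70,
                        max_evalue = 1e-5, k = 12L, seed_gap = 40L,
                        pad = 30L) {
  query <- toupper(as.character(query))
  subject <- toupper(as.character(subject))
  stopifnot(nzchar(query), nzchar(subject))
  nq <- nchar(query); ns <- nchar(subject)
  hits <- list()
  for (strand in c("+", "-")) {
    sseq <- if (strand == "+") subject else .revcompChr(subject)
    if (as.numeric(nq) * ns <= 250000) {
      h <- .refineHit(query, sseq, 1L, nq, 1L, ns, strand, nq, ns)
      if (!is.null(h)) hits[[length(hits) + 1L]] <- h
    } else {
      wins <- .seedWindows(query, sseq, k, seed_gap)
      for (w in wins) {
        qa <- max(1L, w["qa"] - pad); qb <- min(nq, w["qb"] + pad)
        sa <- max(1L, w["qa"] + w["dg"] - pad)
        sb <- min(ns, w["qb"] + w["dg"] + pad)
        h <- .refineHit(query, sseq, qa, qb, sa, sb, strand, nq, ns)
        if (!is.null(h)) hits[[length(hits) + 1L]] <- h
      }
    }
  }
  if (!length(hits)) return(.emptyHits())
  df <- do.call(rbind, hits)
  df <- df[df$identity >= min_identity & df$evalue <= max_evalue, , drop = FALSE]
  if (!nrow(df)) return(.emptyHits())
  ## collapse hits overlapping on both axes to the highest-scoring
  df <- df[order(-df$score), , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))[-1]) {
    for (j in seq_len(i - 1L)) {
      if (!keep[j]) next
      if (df$q_start[i] <= df$q_end[j] && df$q_end[i] >= df$q_start[j] &&
          df$s_start[i] <= df$s_end[j] && df$s_end[i] >= df$s_start[j]) {
        keep[i] <- FALSE; break
      }
    }
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$q_start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Detect chloroplast-derived fragments in a mitochondrial genome
#'
#' Masks protein, tRNA and rRNA gene exons in the mitochondrial genome with
#' N (so conserved housekeeping genes shared by the two organelles cannot
#' hit), searches the masked sequence against the chloroplast genome with
#' [localSearch()] at the configured thresholds, merges hits lying within
#' `merge_gap` bp on both genomes, and annotates each merged fragment with
#' the chloroplast genes it overlaps. A contained gene is `intact` when the
#' fragment fully contains its span (and, for protein genes, the
#' mitochondrial copy retains an open reading frame); otherwise `pseudo`.
#' Fragments are numbered in decreasing length order.
#'
#' @param mt mitochondrial [Genome-class]
#' @param mt_ann its [AnnotationSet-class] (a missing annotation triggers a
#'   loud warning and an unmasked search)
#' @param cp chloroplast [Genome-class]
#' @param cp_ann optional chloroplast [AnnotationSet-class] for gene content
#' @param cfg a [PipelineConfig-class]
#' @param merge_gap merge hits within this distance on both axes, bp
#' @return data.frame: no, length, mt_start, mt_end, cp_start, cp_end,
#'   strand, identity, genes_contained (comma-joined `name(intact|pseudo)`)
#' @export
findCpInsertions <- function(mt, mt_ann = NULL, cp, cp_ann = NULL,
                             cfg = PipelineConfig(), merge_gap = 30L) {
  if (is.null(mt_ann)) {
    warning("no mitochondrial annotation supplied: searching UNMASKED genome; ",
            "hits in conserved genes are expected")
    masked <- genomeString(mt)
  } else {
    masked <- maskFeatures(mt, mt_ann, c("protein", "tRNA", "rRNA"))
  }
  hits <- localSearch(masked, genomeString(cp),
                      min_identity = cfg@mtptMinIdentity,
                      max_evalue = cfg@mtptMaxEvalue)
  if (!nrow(hits)) return(.emptyFragments())
  ## merge hits within merge_gap on both genomes (same strand)
  hits <- hits[order(hits$q_start), , drop = FALSE]
  grp <- integer(nrow(hits)); g <- 0L
  for (i in seq_len(nrow(hits))) {
    assigned <- FALSE
    if (i > 1L) for (j in which(grp[seq_len(i - 1L)] > 0L)) {
      if (hits$strand[i] == hits$strand[j] &&
          hits$q_start[i] - hits$q_end[j] <= merge_gap &&
          abs(hits$s_start[i] - hits$s_end[j]) <= merge_gap +
            (hits$q_start[i] - hits$q_end[j])) {
        grp[i] <- grp[j]; assigned <- TRUE; break
      }
    }
    if (!assigned) { g <- g + 1L; grp[i] <- g }
  }
  frs <- lapply(split(seq_len(nrow(hits)), grp), function(ii) {
    h <- hits[ii, , drop = FALSE]
    data.frame(mt_start = min(h$q_start), mt_end = max(h$q_end),
               cp_start = min(h$s_start), cp_end = max(h$s_end),
               strand = h$strand[1],
               identity = sum(h$matches) / sum(h$aln_length),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, frs)
  df$length <- df$mt_end - df$mt_start + 1L
  df <- df[order(-df$length), , drop = FALSE]
  df$no <- seq_len(nrow(df))
  df$genes_contained <- ""
  if (!is.null(cp_ann)) {
    for (i in seq_len(nrow(df))) {
      cg <- .containedCpGenes(df[i, ], cp_ann, mt)
      df$genes_contained[i] <- cg
    }
  }
  rownames(df) <- NULL
  df[, c("no", "length", "mt_start", "mt_end", "cp_start", "cp_end",
         "strand", "identity", "genes_contained")]
}

.emptyFragments <- function()
  data.frame(no = integer(), length = integer(), mt_start = integer(),
             mt_end = integer(), cp_start = integer(), cp_end = integer(),
             strand = character(), identity = numeric(),
             genes_contained = character(), stringsAsFactors = FALSE)

.containedCpGenes <- function(frag, cp_ann, mt) {
  g <- genes(cp_ann); ex <- exons(cp_ann)
  out <- character()
  for (gid in g$gene_id) {
    e <- ex[mcols(ex)$gene_id == gid]
    gs <- min(start(e)); ge <- max(end(e))
    if (ge < frag$cp_start || gs > frag$cp_end) next
    contained <- gs >= frag$cp_start && ge <= frag$cp_end
    intact <- contained
    if (contained && g$category[g$gene_id == gid] == "protein") {
      ## the mt copy must retain an open reading frame
      off1 <- gs - frag$cp_start; off2 <- ge - frag$cp_start
      mtSub <- if (frag$strand == "+")
        substr(genomeString(mt), frag$mt_start + off1, frag$mt_start + off2)
      else
        .revcompChr(substr(genomeString(mt), frag$mt_end - off2,
                           frag$mt_end - off1))
      intact <- nchar(mtSub) %% 3L == 0L && !.hasInternalStop(mtSub)
    }
    out <- c(out, paste0(g$name[g$gene_id == gid],
                         if (intact) "(intact)" else "(pseudo)"))
  }
  paste(out, collapse = ",")
}

.hasInternalStop <- function(cds) {
  n <- nchar(cds) %/% 3L
  if (n < 2L) return(FALSE)
  cods <- substring(cds, 3L * seq_len(n - 1L) - 2L, 3L * seq_len(n - 1L))
  any(cods %in% c("TAA", "TAG", "TGA"))
}

#' Score fragment presence across other mitochondrial genomes
#'
#' Each fragment's mitochondrial sequence is searched against every genome
#' with [localSearch()]; the best hit per genome is recorded, and the
#' fragment is `present` when best identity >= `homologMinIdentity` and
#' best coverage (alignment length / fragment length) >=
#' `homologMinCoverage`.
#'
#' @param fragments data.frame from [findCpInsertions()]
#' @param mt the mitochondrial [Genome-class] the fragments live on
#' @param other_genomes named list of [Genome-class]
#' @param cfg a [PipelineConfig-class]
#' @return data.frame: fragment_no, species, present, best_identity,
#'   best_coverage
#' @export
findHomologs <- function(fragments, mt, other_genomes, cfg = PipelineConfig()) {
  if (!length(other_genomes) || !nrow(fragments))
    return(data.frame(fragment_no = integer(), species = character(),
                      present = logical(), best_identity = numeric(),
                      best_coverage = numeric()))
  if (is.null(names(other_genomes)))
    names(other_genomes) <- vapply(other_genomes, genomeId, character(1))
  rows <- list()
  for (i in seq_len(nrow(fragments))) {
    fseq <- substr(genomeString(mt), fragments$mt_start[i], fragments$mt_end[i])
    for (sp in names(other_genomes)) {
      h <- localSearch(fseq, genomeString(other_genomes[[sp]]),
                       min_identity = 0, max_evalue = Inf)
      if (nrow(h)) {
        best <- h[which.max(h$score), ]
        ident <- best$identity
        cov <- best$aln_length / nchar(fseq)
      } else { ident <- 0; cov <- 0 }
      rows[[length(rows) + 1L]] <- data.frame(
        fragment_no = fragments$no[i], species = sp,
        present = ident >= cfg@homologMinIdentity &&
                  cov >= cfg@homologMinCoverage,
        best_identity = ident, best_coverage = cov,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
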