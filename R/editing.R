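#' @importFrom Biostrings pairwiseAlignment GENETIC_CODE nucleotideSubstitutionMatrix
NULL

.GLOBAL_SUB <- local({
  m <- matrix(-1, 5, 5, dimnames = list(c("A","C","G","T","N"),
                                        c("A","C","G","T","N")))
  diag(m) <- 1
  m["N", ] <- -1; m[, "N"] <- -1
  m
})

#' Globally align a genomic CDS with its cDNA
#'
#' Needleman-Wunsch global alignment with match +1, mismatch -1, gap open -5,
#' gap extend -2 (a gap of length L costs 5 + 2L). Equal-length colinear
#' inputs align gap-free. A length ratio outside [0.8, 1.25] triggers a
#' warning but the alignment is still returned.
#'
#' @param cds genomic spliced CDS (character)
#' @param cdna cDNA sequence (character)
#' @return list with `dna`, `rna` (aligned strings with `-` gaps),
#'   `score`, and `n_mismatch` (mismatching non-gap columns)
#' @export
alignDnaCdna <- function(cds, cdna) {
  stopifnot(nzchar(cds), nzchar(cdna))
  r <- nchar(cdna) / nchar(cds)
  if (r < 0.8 || r > 1.25)
    warning(sprintf("DNA/cDNA length ratio %.2f outside [0.8, 1.25]", r))
  if (nchar(cds) == nchar(cdna) && cds == cdna) {
    aln <- list(dna = cds, rna = cdna, score = nchar(cds), n_mismatch = 0L)
    return(aln)
  }
  pa <- pairwiseAlignment(cdna, cds, type = "global",
                          substitutionMatrix = .GLOBAL_SUB,
                          gapOpening = 5, gapExtension = 2)
  dna <- as.character(Biostrings::alignedSubject(pa))
  rna <- as.character(Biostrings::alignedPattern(pa))
  d <- strsplit(dna, "")[[1]]; q <- strsplit(rna, "")[[1]]
  nm <- sum(d != q & d != "-" & q != "-")
  list(dna = dna, rna = rna, score = Biostrings::score(pa), n_mismatch = nm)
}

#' Classify the codon effect of a single RNA edit
#'
#' Substitutes the edited base into the reference codon (C->T for C-to-U
#' edits, T->C for U-to-C) and translates both codons with the standard
#' genetic code. The effect is `synonymous` when the amino acid is unchanged
#' and `nonsynonymous` otherwise (stop gains/losses count as nonsynonymous).
#'
#' @param ref_codon reference (DNA-strand) trinucleotide
#' @param codon_pos edited position within the codon, 1..3
#' @param direction `"C2U"` or `"U2C"`
#' @return list: `edited_codon`, `ref_aa`, `edited_aa`, `effect`
#' @examples
#' classifyEdit("TCT", 1, "U2C")   # CCT, S -> P, nonsynonymous
#' classifyEdit("ACC", 3, "C2U")   # ACT, T -> T, synonymous
#' @export
classifyEdit <- function(ref_codon, codon_pos, direction = c("C2U", "U2C")) {
  direction <- match.arg(direction)
  stopifnot(nchar(ref_codon) == 3L, codon_pos %in% 1:3)
  ref_codon <- toupper(ref_codon)
  base <- substr(ref_codon, codon_pos, codon_pos)
  need <- if (direction == "C2U") "C" else "T"
  if (base != need)
    stop(sprintf("codon %s has %s (not %s) at position %d; cannot apply %s",
                 ref_codon, base, need, codon_pos, direction))
  newBase <- if (direction == "C2U") "T" else "C"
  edited <- ref_codon
  substr(edited, codon_pos, codon_pos) <- newBase
  tr <- function(cod) {
    aa <- GENETIC_CODE[cod]
    if (is.na(aa)) NA_character_ else unname(aa)
  }
  refAa <- tr(ref_codon); edAa <- tr(edited)
  list(edited_codon = edited, ref_aa = refAa, edited_aa = edAa,
       effect = if (identical(refAa, edAa)) "synonymous" else "nonsynonymous")
}

.emptySites <- function() {
  data.frame(gene_id = character(), cds_pos = integer(),
             genomic_pos = integer(), direction = character(),
             codon_index = integer(), codon_pos = integer(),
             ref_codon = character(), edited_codon = character(),
             ref_aa = character(), edited_aa = character(),
             effect = character(), stringsAsFactors = FALSE)
}

#' Call RNA-editing sites from a DNA/cDNA pair
#'
#' After global alignment, every column where the DNA has C and the cDNA has
#' T is called a C-to-U edit, and every column where the DNA has T and the
#' cDNA has C a U-to-C edit. All other mismatch columns are reported as
#' non-edit discrepancies (QC output), never as edits. For protein-coding
#' genes each site carries its codon context and effect; for pseudogenes,
#' which lack a reading frame, the effect is `unpartitioned` and codon
#' fields are NA.
#'
#' @param cds genomic spliced CDS of the gene (character)
#' @param cdna cDNA sequence (character)
#' @param gene_id gene identifier recorded on each site
#' @param category gene category (`"protein"` or `"pseudogene"`)
#' @param ann optional [AnnotationSet-class]: when given, sites gain a
#'   `genomic_pos` via [cdsToGenomic()]
#' @return data.frame of editing sites, with attribute `discrepancies`
#'   (data.frame cds_pos/dna/rna) retrievable via [editDiscrepancies()]
#' @export
callEdits <- function(cds, cdna, gene_id, category = "protein", ann = NULL) {
  stopifnot(category %in% c("protein", "pseudogene"))
  aln <- alignDnaCdna(cds, cdna)
  d <- strsplit(aln$dna, "")[[1]]
  q <- strsplit(aln$rna, "")[[1]]
  cdsPos <- cumsum(d != "-")           # CDS coordinate of each column
  mism <- which(d != q & d != "-" & q != "-")
  isC2U <- d[mism] == "C" & q[mism] == "T"
  isU2C <- d[mism] == "T" & q[mism] == "C"
  editCols <- mism[isC2U | isU2C]
  disc <- data.frame(cds_pos = cdsPos[mism[!(isC2U | isU2C)]],
                     dna = d[mism[!(isC2U | isU2C)]],
                     rna = q[mism[!(isC2U | isU2C)]],
                     stringsAsFactors = FALSE)
  if (!length(editCols)) {
    out <- .emptySites()
    attr(out, "discrepancies") <- disc
    return(out)
  }
  pos <- cdsPos[editCols]
  dir <- ifelse(d[editCols] == "C", "C2U", "U2C")
  if (category == "protein") {
    ci <- as.integer(ceiling(pos / 3))
    cp <- as.integer((pos - 1L) %% 3L + 1L)
    refCod <- substring(cds, (ci - 1L) * 3L + 1L, ci * 3L)
    cls <- Map(function(rc, p, dd) {
      if (nchar(rc) < 3L)
        return(list(edited_codon = NA_character_, ref_aa = NA_character_,
                    edited_aa = NA_character_, effect = "unpartitioned"))
      classifyEdit(rc, p, dd)
    }, refCod, cp, dir)
    out <- data.frame(gene_id = gene_id, cds_pos = as.integer(pos),
                      genomic_pos = NA_integer_, direction = dir,
                      codon_index = ci, codon_pos = cp,
                      ref_codon = refCod,
                      edited_codon = vapply(cls, `[[`, character(1), "edited_codon"),
                      ref_aa = vapply(cls, `[[`, character(1), "ref_aa"),
                      edited_aa = vapply(cls, `[[`, character(1), "edited_aa"),
                      effect = vapply(cls, `[[`, character(1), "effect"),
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(gene_id = gene_id, cds_pos = as.integer(pos),
                      genomic_pos = NA_integer_, direction = dir,
                      codon_index = NA_integer_, codon_pos = NA_integer_,
                      ref_codon = NA_character_, edited_codon = NA_character_,
                      ref_aa = NA_character_, edited_aa = NA_character_,
                      effect = "unpartitioned", stringsAsFactors = FALSE)
  }
  if (!is.null(ann))
    out$genomic_pos <- as.integer(cdsToGenomic(ann, gene_id, out$cds_pos))
  rownames(out) <- NULL
  attr(out, "discrepancies") <- disc
  out
}

#' Non-edit DNA/cDNA discrepancies recorded by [callEdits()]
#' @param sites the data.frame returned by [callEdits()]
#' @return data.frame of mismatch columns that are not C<->T pairs
#' @export
editDiscrepancies <- function(sites) {
  d <- attr(sites, "discrepancies")
  if (is.null(d)) data.frame(cds_pos = integer(), dna = character(),
                             rna = character()) else d
}

#' Editing frequency in edits per 100 nt
#'
#' @param n_edits number of edits in the gene
#' @param cds_length spliced CDS length, nt
#' @return edits/100 nt, rounded half-up to 3 decimals
#' @examples
#' editingFrequency(16, 225)  # 7.111
#' @export
editingFrequency <- function(n_edits, cds_length) {
  if (cds_length <= 0) stop("cds_length must be > 0")
  roundHalfUp(100 * n_edits / cds_length, 3)
}

#' Per-gene editing profile
#'
#' @param sites editing-site data.frame (from [callEdits()] rows, combined)
#' @param cds_lengths named integer vector of spliced CDS lengths
#' @return data.frame: gene_id, n_edits, cds_length, freq_per_100nt
#' @export
editingProfile <- function(sites, cds_lengths) {
  ids <- names(cds_lengths)
  n <- vapply(ids, function(g) sum(sites$gene_id == g), integer(1))
  data.frame(gene_id = ids, n_edits = n,
             cds_length = as.integer(cds_lengths),
             freq_per_100nt = vapply(ids, function(g)
               editingFrequency(sum(sites$gene_id == g), cds_lengths[[g]]),
               numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

.baseName <- function(name) {
  x <- sub("\\((cp)\\)$", "", name)
  x <- sub("-cp$", "", x)
  sub("-[12ab]$", "", x)
}

#' Collapse edits of identical duplicated gene copies
#'
#' Gene copies named with the `-1`/`-2` suffix convention are identical by
#' definition; when their spliced CDSs are indeed identical, their edits are
#' reported once, under the lexicographically first copy. Divergent copies
#' (`-a`/`-b`) and copies with differing CDSs are kept separate.
#'
#' @param sites editing-site data.frame
#' @param ann an [AnnotationSet-class] (copy naming)
#' @param cds_seqs named character vector of spliced CDSs
#' @return filtered editing-site data.frame
#' @export
dedupeCopies <- function(sites, ann, cds_seqs) {
  g <- genes(ann)
  dup <- g[grepl("-[12]$", g$name), ]
  if (!nrow(dup) || !nrow(sites)) return(sites)
  drop <- character()
  for (bn in unique(.baseName(dup$name))) {
    ids <- dup$gene_id[.baseName(dup$name) == bn]
    ids <- ids[order(g$name[match(ids, g$gene_id)])]
    if (length(ids) < 2L) next
    rep1 <- ids[1]
    same <- vapply(ids[-1], function(i)
      identical(cds_seqs[[i]], cds_seqs[[rep1]]), logical(1))
    drop <- c(drop, ids[-1][same])
  }
  sites[!(sites$gene_id %in% drop), , drop = FALSE]
}

#' Nonsynonymous share of editing sites
#'
#' Reports both conventions: the share of all sites (nonsynonymous /
#' (nonsynonymous + synonymous + unpartitioned)) and the share of
#' partitioned sites only (pseudogene edits, which lack a reading frame,
#' removed from the denominator).
#'
#' @param n_nonsyn,n_syn,n_unpartitioned site counts
#' @param digits decimal places on the percentages (default 0)
#' @return list: `pct_of_all`, `pct_of_partitioned`, `total`
#' @examples
#' nonsynShare(612, 58, 30)$pct_of_all   # 87
#' @export
nonsynShare <- function(n_nonsyn, n_syn, n_unpartitioned = 0, digits = 0) {
  total <- n_nonsyn + n_syn + n_unpartitioned
  list(pct_of_all = roundHalfUp(100 * n_nonsyn / total, digits),
       pct_of_partitioned = roundHalfUp(100 * n_nonsyn / (n_nonsyn + n_syn),
                                        digits),
       total = total)
}

#' Compare editing-site sets of two species over shared genes
#'
#' For every gene present (by name) in both species, the two spliced CDSs
#' are globally aligned and each edit is mapped to its alignment column. An
#' edit is shared when both species carry an edit in the same column; an
#' edit aligned to a gap in the other species is unique by definition.
#' Totals are summed over shared genes; genes present in only one species
#' are excluded (and listed in the result).
#'
#' @param sites_a,sites_b editing-site data.frames (gene_id, cds_pos)
#' @param cds_a,cds_b named character vectors of spliced CDSs per species
#' @return list: `n_shared`, `n_unique_a`, `n_unique_b`, `per_gene`
#'   data.frame, `excluded_genes`
#' @export
compareEditingSets <- function(sites_a, cds_a, sites_b, cds_b) {
  shared <- intersect(names(cds_a), names(cds_b))
  excluded <- setdiff(union(names(cds_a), names(cds_b)), shared)
  nS <- 0L; uA <- 0L; uB <- 0L
  per <- list()
  for (g in shared) {
    aln <- alignDnaCdna(cds_a[[g]], cds_b[[g]])
    a <- strsplit(aln$dna, "")[[1]]   # species a CDS is the 'subject'
    b <- strsplit(aln$rna, "")[[1]]
    colOfA <- which(a != "-")          # alignment column of each a position
    colOfB <- which(b != "-")
    pa <- sites_a$cds_pos[sites_a$gene_id == g]
    pb <- sites_b$cds_pos[sites_b$gene_id == g]
    ca <- colOfA[pa]; cb <- colOfB[pb]
    s <- length(intersect(ca, cb))
    nS <- nS + s
    uA <- uA + length(ca) - s
    uB <- uB + length(cb) - s
    per[[g]] <- data.frame(gene = g, shared = s,
                           unique_a = length(ca) - s,
                           unique_b = length(cb) - s)
  }
  list(n_shared = nS, n_unique_a = uA, n_unique_b = uB,
       per_gene = if (length(per)) do.call(rbind, per) else NULL,
       excluded_genes = excluded)
}

#' Run the full editing analysis over an annotated genome and cDNA set
#'
#' Splices each protein-coding or pseudogene CDS, calls edits against the
#' matching cDNA, collapses identical duplicated copies, and computes the
#' per-gene profile. Genes without a cDNA are skipped and listed. A gene
#' whose cDNA is flagged as pre-mRNA (name in `premrna_genes`) is compared
#' against its unspliced genomic span instead of the spliced CDS.
#'
#' @param genome a [Genome-class]
#' @param ann an [AnnotationSet-class]
#' @param cdna named character vector (gene_id -> cDNA)
#' @param premrna_genes gene_ids whose amplicon is pre-mRNA (unspliced)
#' @return list: `sites` (deduped), `profile`, `skipped`, `discrepancies`,
#'   `effect_counts`
#' @export
runEditingAnalysis <- function(genome, ann, cdna, premrna_genes = character()) {
  g <- genes(ann)
  g <- g[g$category %in% c("protein", "pseudogene"), , drop = FALSE]
  skipped <- setdiff(g$gene_id, names(cdna))
  if (length(skipped))
    message("skipping genes without cDNA: ", paste(skipped, collapse = ", "))
  use <- intersect(g$gene_id, names(cdna))
  cds <- vapply(use, function(gid) {
    if (gid %in% premrna_genes) {
      e <- geneExons(ann, gid)
      s <- subseq(genomeSeq(genome), min(start(e)), max(end(e)))
      if (as.character(strand(e))[1] == "-") s <- reverseComplement(s)
      as.character(s)
    } else spliceCds(genome, ann, gid)
  }, character(1))
  names(cds) <- use
  all <- list(); disc <- list()
  for (gid in use) {
    s <- callEdits(cds[[gid]], cdna[[gid]], gid,
                   category = g$category[g$gene_id == gid], ann = ann)
    disc[[gid]] <- editDiscrepancies(s)
    all[[gid]] <- s
  }
  sites <- do.call(rbind, c(all, list(make.row.names = FALSE)))
  if (is.null(sites)) sites <- .emptySites()
  sites <- dedupeCopies(sites, ann, cds)
  ## duplicated identical copies count once in the profile denominator too
  keep <- use[!duplicated(unname(cds[use]))]
  prof <- editingProfile(sites, vapply(keep, function(i) nchar(cds[[i]]),
                                       integer(1)))
  eff <- table(factor(sites$effect,
                      levels = c("nonsynonymous", "synonymous", "unpartitioned")))
  list(sites = sites, profile = prof, skipped = skipped,
       discrepancies = disc, effect_counts = as.list(eff))
}
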