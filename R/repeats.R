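#' @importFrom Biostrings DNAString reverseComplement
NULL

.revcompChr <- function(x)
  as.character(reverseComplement(DNAString(x)))

.leastRotation <- function(unit) {
  k <- nchar(unit)
  if (k == 1L) return(unit)
  rots <- vapply(seq_len(k), function(i)
    paste0(substr(unit, i, k), substr(unit, 1, i - 1L)), character(1))
  sort(rots)[1]
}

.isPrimitive <- function(unit) {
  k <- nchar(unit)
  if (k == 1L) return(TRUE)
  for (d in seq_len(k - 1L)) {
    if (k %% d == 0L && unit == strrep(substr(unit, 1, d), k %/% d))
      return(FALSE)
  }
  TRUE
}

.circularOverhang <- function(n) min(n, 600L)

#' Find perfect simple sequence repeats (microsatellites)
#'
#' Reports every maximal perfect tandem repeat of a 1-6 nt unit meeting the
#' per-unit-length minimum count. A run whose unit is a power of a shorter
#' unit (e.g. `ATAT`) is reported at the smallest unit length only. Motifs
#' are reported as observed, with the lexicographically least rotation in
#' `motif_canonical`. Mononucleotide runs of N are never SSRs. Circular
#' genomes are scanned with a `min(length, 600)`-bp overhang appended so
#' origin-spanning loci are caught; loci wholly inside the overhang copy are
#' dropped and wrapping loci report `end > genome length` with `wraps =
#' TRUE`.
#'
#' @param genome a [Genome-class] (or plain character sequence, treated as
#'   linear)
#' @param min_units integer vector of minimum unit counts for unit lengths
#'   1..6
#' @return data.frame: motif, motif_canonical, unit_len, n_units, start,
#'   end, wraps
#' @export
findSsrs <- function(genome, min_units = c(10L, 5L, 4L, 3L, 3L, 3L)) {
  stopifnot(length(min_units) == 6L)
  if (is(genome, "Genome")) {
    s <- genomeString(genome)
    circular <- topology(genome) == "circular"
  } else {
    s <- toupper(as.character(genome)); circular <- FALSE
  }
  n <- nchar(s)
  ext <- if (circular) paste0(s, substr(s, 1, .circularOverhang(n))) else s
  ch <- strsplit(ext, "")[[1]]
  N <- length(ch)
  out <- list()
  for (k in 1:6) {
    if (N <= k) next
    m <- ch[(k + 1L):N] == ch[1:(N - k)]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (idx in which(r$values & r$lengths >= k * (min_units[k] - 1L))) {
      a <- starts[idx]
      span <- r$lengths[idx] + k
      nu <- span %/% k
      if (nu < min_units[k]) next
      unit <- substr(ext, a, a + k - 1L)
      if (grepl("N", unit, fixed = TRUE)) next
      if (!.isPrimitive(unit)) next
      out[[length(out) + 1L]] <- data.frame(
        motif = unit, motif_canonical = .leastRotation(unit),
        unit_len = k, n_units = nu, start = a,
        end = a + nu * k - 1L, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(motif = character(), motif_canonical = character(),
                      unit_len = integer(), n_units = integer(),
                      start = integer(), end = integer(), wraps = logical()))
  df <- do.call(rbind, out)
  if (circular) {
    df <- df[df$start <= n, , drop = FALSE]
    ## drop loci that are modular duplicates of (contained in) a wrapping run
    if (nrow(df)) {
      keep <- rep(TRUE, nrow(df))
      wrapping <- which(df$end > n)
      for (w in wrapping) {
        dup <- df$unit_len == df$unit_len[w] &
          (df$start + n) >= df$start[w] & (df$end + n) <= df$end[w]
        keep[dup] <- FALSE
      }
      df <- df[keep, , drop = FALSE]
    }
  }
  df$wraps <- df$end > n
  df <- df[order(df$start, df$unit_len), , drop = FALSE]
  rownames(df) <- NULL
  df
}

## X-drop ungapped extension; returns best-scoring symmetric extension
## lengths (left, right) for loci starting/ending at the given coordinates.
.xdropExtend <- function(chA, chB, a1, a2, b1, b2, xdrop = 12L,
                         mismatchPenalty = 3L) {
  extend <- function(stepA, stepB, fromA, fromB) {
    best <- 0L; bestLen <- 0L; sc <- 0L; len <- 0L
    repeat {
      pa <- fromA + stepA * (len + 1L)
      pb <- fromB + stepB * (len + 1L)
      if (pa < 1L || pb < 1L || pa > length(chA) || pb > length(chB)) break
      len <- len + 1L
      sc <- sc + if (chA[pa] == chB[pb] && chA[pa] != "N") 1L else -mismatchPenalty
      if (sc > best) { best <- sc; bestLen <- len }
      if (best - sc > xdrop) break
    }
    bestLen
  }
  list(left = extend(-1L, -1L, a1, b1), right = extend(1L, 1L, a2, b2))
}

#' Find long direct and inverted repeats
#'
#' Exact-seed (k-mer anchor) detection with ungapped X-drop extension:
#' shared k-mers are clustered on diagonals, extended to the best-scoring
#' span, and reported when the alignment length strictly exceeds `min_len`
#' and the ungapped identity meets `min_identity`. Both orientations are
#' scanned (inverted = reverse-complement copy). Self-hits are excluded and
#' symmetric duplicates collapsed; `interval_a` always precedes
#' `interval_b`. Circular genomes get a `min(length, 600)`-bp overhang, with
#' modular deduplication.
#'
#' @param genome a [Genome-class] or character sequence
#' @param min_len repeats must be strictly longer than this (bp)
#' @param min_identity identity floor, fraction
#' @param k seed k-mer length (31 by default; exactness of recovery at the
#'   99\% identity floor is bounded by the brute-force oracle tests)
#' @param seed_gap merge seeds on the same diagonal within this gap (bp)
#' @return data.frame: kind, start_a, end_a, start_b, end_b, length,
#'   identity
#' @export
findLongRepeats <- function(genome, min_len = 500, min_identity = 0.99,
                            k = 31L, seed_gap = 100L) {
  if (is(genome, "Genome")) {
    s <- genomeString(genome)
    circular <- topology(genome) == "circular"
  } else {
    s <- toupper(as.character(genome)); circular <- FALSE
  }
  n <- nchar(s)
  if (n < 2L * k) return(.emptyRepeats())
  ext <- if (circular) paste0(s, substr(s, 1, .circularOverhang(n))) else s
  N <- nchar(ext)
  chF <- strsplit(ext, "")[[1]]
  pos <- 1:(N - k + 1L)
  kmF <- substring(ext, pos, pos + k - 1L)
  okF <- !grepl("N", kmF, fixed = TRUE)
  idxF <- split(pos[okF], kmF[okF])
  idxF <- idxF[lengths(idxF) <= 50L]   # skip pathological low-complexity seeds
  rows <- list()

  harvest <- function(pairsI, pairsJ, kind, chB) {
    if (!length(pairsI)) return()
    d <- pairsJ - pairsI
    for (dg in unique(d)) {
      ii <- sort(pairsI[d == dg])
      br <- c(0L, which(diff(ii) > seed_gap), length(ii))
      for (ci in seq_len(length(br) - 1L)) {
        grp <- ii[(br[ci] + 1L):br[ci + 1L]]
        a1 <- grp[1]; a2 <- grp[length(grp)] + k - 1L
        b1 <- a1 + dg; b2 <- a2 + dg
        extn <- .xdropExtend(chF, chB, a1, a2, b1, b2)
        a1 <- a1 - extn$left; b1 <- b1 - extn$left
        a2 <- a2 + extn$right; b2 <- b2 + extn$right
        len <- a2 - a1 + 1L
        ident <- mean(chF[a1:a2] == chB[b1:b2])
        rows[[length(rows) + 1L]] <<- data.frame(
          kind = kind, a1 = a1, a2 = a2, b1 = b1, b2 = b2,
          length = len, identity = ident, stringsAsFactors = FALSE)
      }
    }
  }

  ## direct: pairs of identical forward k-mers, i < j
  pi <- integer(); pj <- integer()
  for (p in idxF[lengths(idxF) >= 2L]) {
    cmb <- utils::combn(p, 2L)
    pi <- c(pi, cmb[1, ]); pj <- c(pj, cmb[2, ])
  }
  harvest(pi, pj, "direct", chF)

  ## inverted: forward k-mers matching k-mers of the reverse complement
  rcs <- .revcompChr(ext)
  chR <- strsplit(rcs, "")[[1]]
  kmR <- substring(rcs, pos, pos + k - 1L)
  okR <- !grepl("N", kmR, fixed = TRUE)
  idxR <- split(pos[okR], kmR[okR])
  idxR <- idxR[lengths(idxR) <= 50L]
  common <- intersect(names(idxF), names(idxR))
  pi <- integer(); pj <- integer()
  for (km in common) {
    grid <- expand.grid(i = idxF[[km]], j = idxR[[km]])
    pi <- c(pi, grid$i); pj <- c(pj, grid$j)
  }
  harvest(pi, pj, "inverted", chR)

  if (!length(rows)) return(.emptyRepeats())
  df <- do.call(rbind, rows)
  ## map inverted second locus from reverse-complement to forward coordinates
  inv <- df$kind == "inverted"
  if (any(inv)) {
    b1 <- N - df$b2[inv] + 1L; b2 <- N - df$b1[inv] + 1L
    df$b1[inv] <- b1; df$b2[inv] <- b2
  }
  ## canonical order: interval_a starts first; drop self-hits/overlaps
  flip <- df$b1 < df$a1
  tmp <- df[flip, c("b1", "b2", "a1", "a2")]
  df[flip, c("a1", "a2", "b1", "b2")] <- tmp
  df <- df[!(df$a1 == df$b1 & df$a2 == df$b2), , drop = FALSE]
  df <- df[df$b1 > df$a2, , drop = FALSE]        # distinct, non-overlapping loci
  df <- df[df$length > min_len & df$identity >= min_identity, , drop = FALSE]
  if (circular && nrow(df)) {
    ## modular dedup: shift loci fully beyond the origin back
    over <- df$a1 > n
    df$a1[over] <- df$a1[over] - n; df$a2[over] <- df$a2[over] - n
    over <- df$b1 > n
    df$b1[over] <- df$b1[over] - n; df$b2[over] <- df$b2[over] - n
    flip <- df$b1 < df$a1
    tmp <- df[flip, c("b1", "b2", "a1", "a2")]
    df[flip, c("a1", "a2", "b1", "b2")] <- tmp
    df <- df[!(df$a1 == df$b1 & df$a2 == df$b2), , drop = FALSE]
  }
  df <- unique(df)
  ## containment: keep only maximal pairs
  if (nrow(df) > 1L) {
    o <- order(-df$length)
    df <- df[o, , drop = FALSE]
    keep <- rep(TRUE, nrow(df))
    for (i in seq_len(nrow(df))[-1]) {
      for (j in seq_len(i - 1L)) {
        if (!keep[j] || df$kind[i] != df$kind[j]) next
        if (df$a1[i] >= df$a1[j] && df$a2[i] <= df$a2[j] &&
            df$b1[i] >= df$b1[j] && df$b2[i] <= df$b2[j]) {
          keep[i] <- FALSE; break
        }
      }
    }
    df <- df[keep, , drop = FALSE]
  }
  out <- data.frame(kind = df$kind, start_a = df$a1, end_a = df$a2,
                    start_b = df$b1, end_b = df$b2, length = df$length,
                    identity = df$identity, stringsAsFactors = FALSE)
  out <- out[order(out$start_a, out$start_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.emptyRepeats <- function()
  data.frame(kind = character(), start_a = integer(), end_a = integer(),
             start_b = integer(), end_b = integer(), length = integer(),
             identity = numeric(), stringsAsFactors = FALSE)

#' Write SSR loci as BED
#'
#' Conversion to BED's 0-based half-open coordinates happens only here.
#'
#' @param ssrs data.frame from [findSsrs()]
#' @param genome_id sequence name for column 1
#' @param path output path
#' @export
writeSsrBed <- function(ssrs, genome_id, path) {
  bed <- data.frame(chrom = genome_id, start = ssrs$start - 1L,
                    end = ssrs$end,
                    name = paste0("(", ssrs$motif, ")", ssrs$n_units))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
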