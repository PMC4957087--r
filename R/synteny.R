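#' Gene order of an annotated genome
#'
#' Genes are ordered by the start of their leftmost exon. Trans-spliced
#' genes contribute one entry per genomically contiguous exon group,
#' suffixed with the coding-order indices of the group (e.g.
#' `nad1_exon2,3`), since their pieces occupy independent loci.
#'
#' @param ann an [AnnotationSet-class]
#' @param circular is the underlying genome circular?
#' @param categories gene categories to include
#' @return data.frame of class `GeneOrder`: name, strand, start; attribute
#'   `circular`
#' @export
geneOrder <- function(ann, circular = TRUE,
                      categories = c("protein", "tRNA", "rRNA", "pseudogene")) {
  g <- genes(ann)
  g <- g[g$category %in% categories, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(g))) {
    e <- geneExons(ann, g$gene_id[i])
    if (isTRUE(g$trans_spliced[i]) && length(e) > 1L) {
      ## split into genomically contiguous, same-strand exon groups
      o <- order(start(e))
      brk <- cumsum(c(1L, as.integer(
        diff(start(e)[o]) > 2000L |
          as.character(strand(e))[o][-1] != as.character(strand(e))[o][-length(e)])))
      for (grp in unique(brk)) {
        idx <- o[brk == grp]
        co <- sort(mcols(e)$coding_order[idx])
        rows[[length(rows) + 1L]] <- data.frame(
          name = paste0(g$name[i], "_exon", paste(co, collapse = ",")),
          strand = as.character(strand(e))[idx[1]],
          start = min(start(e)[idx]), stringsAsFactors = FALSE)
      }
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        name = g$name[i], strand = as.character(strand(e))[1],
        start = min(start(e)), stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "circular") <- circular
  class(df) <- c("GeneOrder", class(df))
  df
}

#' Build a gene order from name/strand vectors
#'
#' Convenience for fixture-style inputs (two-column name/strand tables).
#'
#' @param names gene names, in genomic order
#' @param strands strand per gene (`+`/`-`), recycled
#' @param circular circular order?
#' @return a `GeneOrder` data.frame
#' @export
geneOrderFromNames <- function(names, strands = "+", circular = FALSE) {
  df <- data.frame(name = as.character(names),
                   strand = rep_len(strands, length(names)),
                   start = seq_along(names), stringsAsFactors = FALSE)
  attr(df, "circular") <- circular
  class(df) <- c("GeneOrder", class(df))
  df
}

## Name matching ignores the identical-copy suffixes -1/-2, the
## divergent-copy suffixes -a/-b, and the plastid-origin tags -cp / (cp);
## organelle gene nomenclature is standardized, so name-level matching
## stands in for protein-similarity matching.
.syntenyKey <- function(name) {
  x <- gsub("\\(cp\\)", "", name)
  x <- sub("-cp$", "", x)
  sub("-[12ab]$", "", x)
}

#' Restrict two gene orders to their shared genes
#'
#' @param order_a,order_b `GeneOrder` data.frames
#' @return list of the two projected orders (columns gain a `key`)
#' @export
projectShared <- function(order_a, order_b) {
  ka <- .syntenyKey(order_a$name); kb <- .syntenyKey(order_b$name)
  shared <- intersect(ka, kb)
  pa <- order_a[ka %in% shared, , drop = FALSE]
  pb <- order_b[kb %in% shared, , drop = FALSE]
  pa$key <- .syntenyKey(pa$name); pb$key <- .syntenyKey(pb$name)
  attr(pa, "circular") <- attr(order_a, "circular")
  attr(pb, "circular") <- attr(order_b, "circular")
  rownames(pa) <- rownames(pb) <- NULL
  list(a = pa, b = pb)
}

#' Find collinear gene clusters between two gene orders
#'
#' After projection onto the shared gene set, reports every maximal run of
#' two or more genes that are consecutive in order A and consecutive
#' (within `max_gap` intervening shared genes) in order B, in the same or
#' exactly reversed order. Circular orders are scanned across the origin.
#' Orientation is `same` when the B positions increase along the run and
#' `inverted` when they decrease; strand agreement is not required for
#' membership.
#'
#' @param order_a,order_b `GeneOrder` data.frames
#' @param max_gap allowed intervening shared genes in B between cluster
#'   neighbours (0 = strict adjacency)
#' @return data.frame: genes (hyphen-joined run, A order), size, orientation
#' @export
findClusters <- function(order_a, order_b, max_gap = 0L) {
  pr <- projectShared(order_a, order_b)
  a <- pr$a; b <- pr$b
  nA <- nrow(a); nB <- nrow(b)
  if (nA < 2L || nB < 2L)
    return(data.frame(genes = character(), size = integer(),
                      orientation = character(), stringsAsFactors = FALSE))
  posB <- split(seq_len(nB), b$key)   # key -> positions in b
  circA <- isTRUE(attr(a, "circular"))
  circB <- isTRUE(attr(b, "circular"))
  idxSeq <- if (circA) c(seq_len(nA), seq_len(nA)) else seq_len(nA)
  step <- max_gap + 1L
  ## adjacency in circular B wraps around
  adjacent <- function(p, q) {
    d <- q - p
    if (abs(d) <= step && d != 0L) return(as.integer(sign(d)))
    if (circB) {
      if (d > 0 && nB - d <= step) return(-1L)   # wraps backwards
      if (d < 0 && nB + d <= step) return(1L)
    }
    0L
  }
  clusters <- list()
  i <- 1L
  while (i < length(idxSeq)) {
    ## try to grow a run starting at idxSeq[i]
    run <- idxSeq[i]
    bpos <- posB[[a$key[idxSeq[i]]]]
    dirs <- NULL
    j <- i
    curB <- NULL
    while (j < length(idxSeq) && length(run) < nA) {
      nxt <- idxSeq[j + 1L]
      cand <- posB[[a$key[nxt]]]
      extended <- FALSE
      for (pb in bpos) for (qb in cand) {
        d <- adjacent(pb, qb)
        if (d == 0L) next
        if (is.null(dirs) || d == dirs) {
          run <- c(run, nxt); bpos <- qb; dirs <- d
          extended <- TRUE; break
        }
      }
      if (!extended) break
      j <- j + 1L
    }
    if (length(run) >= 2L) {
      clusters[[length(clusters) + 1L]] <- list(run = run, dir = dirs)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(clusters))
    return(data.frame(genes = character(), size = integer(),
                      orientation = character(), stringsAsFactors = FALSE))
  out <- lapply(clusters, function(cl) {
    nm <- a$name[cl$run]
    data.frame(genes = paste(nm, collapse = "-"),
               size = length(cl$run),
               orientation = if (isTRUE(cl$dir == -1L)) "inverted" else "same",
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  keySets <- lapply(clusters, function(cl) unique(a$key[cl$run]))
  dup <- duplicated(df)
  df <- df[!dup, , drop = FALSE]; keySets <- keySets[!dup]
  ## a circular doubled scan can report a run twice or as a rotated
  ## sub-run; drop clusters whose gene set is contained in a larger one
  o <- order(-df$size)
  df <- df[o, , drop = FALSE]; keySets <- keySets[o]
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))[-1]) {
    for (j in seq_len(i - 1L)) {
      if (keep[j] && all(keySets[[i]] %in% keySets[[j]])) {
        keep[i] <- FALSE; break
      }
    }
  }
  df <- df[keep, , drop = FALSE]
  df$size <- pmin(df$size, nA)
  rownames(df) <- NULL
  df
}
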