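## Independent oracles used across the suite. These deliberately share no
## code with the package implementations they check.

randSeq <- function(n, seed = NULL, bases = c("A", "C", "G", "T")) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

## exhaustive Smith-Waterman best local score with affine gaps
## (gap of length L costs gapOpen + L * gapExt), +1 match, -2 mismatch
swOracleScore <- function(q, s, match = 1, mism = -2, gapOpen = 5, gapExt = 2) {
  qq <- strsplit(q, "")[[1]]; ss <- strsplit(s, "")[[1]]
  n <- length(qq); m <- length(ss)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - gapOpen - gapExt, E[i, j - 1] - gapExt)
      F[i, j] <- max(H[i - 1, j] - gapOpen - gapExt, F[i - 1, j] - gapExt)
      sub <- if (qq[i - 1] == ss[j - 1]) match else mism
      H[i, j] <- max(0, H[i - 1, j - 1] + sub, E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

## brute-force SSR enumeration: at every start and unit length, count full
## units by direct substring comparison; keep runs that meet the threshold,
## have a primitive N-free unit, and are not extendable by a full unit on
## the left (i.e. are run starts)
ssrOracle <- function(s, min_units = c(10L, 5L, 4L, 3L, 3L, 3L)) {
  n <- nchar(s)
  ch <- strsplit(s, "")[[1]]
  prim <- function(u) {
    k <- nchar(u)
    if (k == 1L) return(TRUE)
    for (d in seq_len(k - 1L))
      if (k %% d == 0L && u == strrep(substr(u, 1, d), k / d)) return(FALSE)
    TRUE
  }
  out <- list()
  for (k in 1:6) {
    i <- 1L
    while (i + k * min_units[k] - 1L <= n + k - 1L && i <= n - k + 1L) {
      ## left-maximality at period k: position i-1 must not continue the run
      if (i > 1L && i + k - 1L <= n && ch[i - 1L] == ch[i + k - 1L]) {
        i <- i + 1L; next
      }
      unit <- substr(s, i, i + k - 1L)
      if (nchar(unit) < k || grepl("N", unit) || !prim(unit)) { i <- i + 1L; next }
      nu <- 1L
      while (i + (nu + 1L) * k - 1L <= n &&
             substr(s, i + nu * k, i + (nu + 1L) * k - 1L) == unit)
        nu <- nu + 1L
      if (nu >= min_units[k])
        out[[length(out) + 1L]] <- data.frame(
          motif = unit, unit_len = k, n_units = nu, start = i,
          end = i + nu * k - 1L, stringsAsFactors = FALSE)
      i <- i + 1L
    }
  }
  if (!length(out))
    return(data.frame(motif = character(), unit_len = integer(),
                      n_units = integer(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  df[order(df$start, df$unit_len), , drop = FALSE]
}

## translate-and-compare oracle for edit-effect classification
effectOracle <- function(codon, pos, direction) {
  code <- Biostrings::GENETIC_CODE
  newBase <- if (direction == "C2U") "T" else "C"
  edited <- codon
  substr(edited, pos, pos) <- newBase
  if (unname(code[codon]) == unname(code[edited])) "synonymous" else "nonsynonymous"
}

## a small simulated bundle, kept cheap for multi-seed loops
smallBundle <- function(seed, noise_rate = 0, n_edits = 25L) {
  simulateBundle(PipelineConfig(rngSeed = seed), n_genes = 8L,
                 mt_len = 14000L, cp_len = 8000L, n_edits = n_edits,
                 n_u2c = 2L, fragment_lengths = c(600L, 250L, 54L),
                 repeat_spec = data.frame(kind = c("direct", "inverted"),
                                          length = c(550L, 520L)),
                 ssr_spec = data.frame(motif = c("A", "AT", "AGC"),
                                       n_units = c(11L, 6L, 5L)),
                 noise_rate = noise_rate)
}

editKey <- function(df) sort(paste(df$gene_id, df$cds_pos, df$direction))
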