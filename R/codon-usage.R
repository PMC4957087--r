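#' @importFrom Biostrings GENETIC_CODE
NULL

.codonSplit <- function(cds, label = "sequence") {
  if (nchar(cds) %% 3L != 0L)
    stop("CDS length of '", label, "' is not divisible by 3")
  n <- nchar(cds) %/% 3L
  substring(toupper(cds), 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Relative synonymous codon usage over a set of CDSs
#'
#' Codon counts are aggregated over all sequences; families are the
#' synonymous codon groups of the standard genetic code, with the three stop
#' codons forming their own family. RSCU for a codon is its observed count
#' divided by the mean count of its family; within each used family the
#' RSCU values sum to the family size. Families with zero total usage get
#' `NA` (0/0 is undefined, not zero). Codons containing ambiguous bases are
#' excluded from the counts with a message.
#'
#' @param cds_list character vector (or list) of CDS sequences, each with
#'   length divisible by 3
#' @return data.frame: codon, aa, count, rscu (64 rows, codon-sorted)
#' @examples
#' computeRscu("TTATTGTTA")[c("TTA", "TTG"), ]  # rscu 4 and 2
#' @export
computeRscu <- function(cds_list) {
  cds_list <- as.character(cds_list)
  labels <- if (!is.null(names(cds_list))) names(cds_list)
            else as.character(seq_along(cds_list))
  codons <- unlist(lapply(seq_along(cds_list), function(i)
    .codonSplit(cds_list[[i]], labels[i])))
  ok <- grepl("^[ACGT]{3}$", codons)
  if (any(!ok))
    message(sum(!ok), " codon(s) with ambiguous bases excluded")
  codons <- codons[ok]
  allCod <- names(GENETIC_CODE)
  counts <- table(factor(codons, levels = allCod))
  aa <- unname(GENETIC_CODE[allCod])
  rscu <- rep(NA_real_, 64)
  for (a in unique(aa)) {
    idx <- which(aa == a)
    tot <- sum(counts[idx])
    if (tot > 0) rscu[idx] <- as.numeric(counts[idx]) / (tot / length(idx))
  }
  out <- data.frame(codon = allCod, aa = aa, count = as.integer(counts),
                    rscu = rscu, stringsAsFactors = FALSE)
  rownames(out) <- allCod
  out
}

#' Fraction of codons with A or T at the third position
#'
#' @param cds_list character vector of CDS sequences
#' @param include_stop count stop codons in the denominator (default TRUE)
#' @return percent, rounded half-up to 2 decimals
#' @export
thirdPositionAT <- function(cds_list, include_stop = TRUE) {
  cds_list <- as.character(cds_list)
  labels <- if (!is.null(names(cds_list))) names(cds_list)
            else as.character(seq_along(cds_list))
  codons <- unlist(lapply(seq_along(cds_list), function(i)
    .codonSplit(cds_list[[i]], labels[i])))
  codons <- codons[grepl("^[ACGT]{3}$", codons)]
  if (!include_stop)
    codons <- codons[GENETIC_CODE[codons] != "*"]
  if (!length(codons)) stop("no valid codons")
  third <- substr(codons, 3, 3)
  roundHalfUp(100 * mean(third %in% c("A", "T")), 2)
}

#' Write an RSCU table as TSV
#' @param rscu data.frame from [computeRscu()]
#' @param path output path
#' @export
writeRscuTsv <- function(rscu, path) {
  utils::write.table(rscu, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
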