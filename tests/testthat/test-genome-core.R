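test_that("half-up rounding and derived genome statistics are exact", {
  expect_equal(roundHalfUp(2.5), 3)
  expect_equal(roundHalfUp(0.125, 2), 0.13)
  expect_equal(roundHalfUp(-2.5), -3)

  expect_equal(gcPercent(Genome("g", "GGCC")), 100)
  ## N counts toward length, not toward G+C
  expect_equal(gcPercent(Genome("g", "GGNN")), 50)

  expect_identical(coverageDepth(31112098, 524797), 59L)
  expect_identical(coverageDepth(100, 100), 1L)
  expect_error(coverageDepth(100, 0))

  expect_identical(meanReadLength(42623117, 9165), 4651L)
  expect_identical(meanReadLength(31112098, 7151), 4351L)

  expect_equal(validationAccuracy(1, 20176), 99.995)
  expect_equal(validationAccuracy(0, 100), 100)
  expect_equal(validationAccuracy(50, 100), 50)
  expect_error(validationAccuracy(1, 0))
  expect_error(validationAccuracy(5, 4))
})

test_that("published per-class percentages are reproduced from printed bp totals", {
  tab <- lotusFeatureTable()
  for (i in seq_len(nrow(tab)))
    expect_equal(percentOfGenome(tab$total_bp[i], 524797L), tab$printed_percent[i],
                 info = tab$category[i])
  expect_equal(roundHalfUp(100 * 252718 / 524797, 2), 48.16)
  expect_equal(percentOfGenome(20176, 524797, 2), 3.84)
})

toyGenome <- function() Genome("toy", "AAACGTCGTAAA")

toyAnn <- function(genome, strand = "+", starts = 5, ends = 10,
                   coding = seq_along(starts), gene = "g1",
                   category = "protein", trans = FALSE) {
  genes <- data.frame(gene_id = unique(gene), name = unique(gene),
                      category = category, origin = "native",
                      trans_spliced = trans, stringsAsFactors = FALSE)
  ex <- GenomicRanges::GRanges(genomeId(genome),
                               IRanges::IRanges(starts, ends),
                               strand = strand)
  S4Vectors::mcols(ex)$gene_id <- gene
  S4Vectors::mcols(ex)$coding_order <- coding
  AnnotationSet(genome, genes, ex)
}

test_that("spliced CDS extraction honours strand and coding order", {
  g <- toyGenome()
  expect_identical(spliceCds(g, toyAnn(g, "+"), "g1"), "GTCGTA")
  expect_identical(spliceCds(g, toyAnn(g, "-"), "g1"), "TACGAC")

  ## trans-spliced two-segment gene on a 60-bp genome: manual concatenation
  s <- randSeq(60, seed = 7)
  g2 <- Genome("t", s)
  ann <- toyAnn(g2, strand = c("+", "-"), starts = c(5, 40), ends = c(16, 51),
                coding = c(1, 2), gene = c("gt", "gt"), trans = TRUE)
  expected <- paste0(substr(s, 5, 16), revcomp(substr(s, 40, 51)))
  expect_identical(spliceCds(g2, ann, "gt"), expected)

  ## splice length always equals the exon-width sum
  expect_identical(nchar(spliceCds(g2, ann, "gt")), 24L)
})

test_that("CDS-to-genome projection inverts splicing", {
  s <- randSeq(60, seed = 8)
  g <- Genome("t", s)
  ann <- toyAnn(g, strand = c("-", "-"), starts = c(30, 10), ends = c(41, 21),
                coding = c(1, 2), gene = c("gm", "gm"))
  cds <- spliceCds(g, ann, "gm")
  ch <- strsplit(s, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (p in seq_len(nchar(cds))) {
    gp <- cdsToGenomic(ann, "gm", p)
    expect_identical(unname(comp[ch[gp]]), substr(cds, p, p))
  }
  ## projected positions cover exactly the exon positions
  expect_setequal(cdsToGenomic(ann, "gm", seq_len(nchar(cds))),
                  c(30:41, 10:21))
})

test_that("feature masking preserves length and masks the interval union", {
  g <- Genome("g", "AAAAA")
  ann <- toyAnn(g, starts = 2, ends = 4)
  expect_identical(maskFeatures(g, ann), "ANNNA")

  ## no masked categories present -> unchanged
  ann2 <- toyAnn(g, starts = 2, ends = 4, category = "orf")
  expect_identical(maskFeatures(g, ann2), "AAAAA")

  ## overlapping genes: N count equals the size of the position-set union
  s <- randSeq(200, seed = 9)
  g3 <- Genome("g3", s)
  ann3 <- toyAnn(g3, starts = c(20, 50, 60), ends = c(70, 90, 65),
                 coding = c(1, 1, 1), gene = c("a", "b", "c"))
  masked <- maskFeatures(g3, ann3)
  expect_identical(nchar(masked), 200L)
  union <- unique(c(20:70, 50:90, 60:65))
  expect_identical(sum(strsplit(masked, "")[[1]] == "N"), length(union))
})

test_that("genome summary computes class totals, intron bp and percentages", {
  expect_equal(summarizeGenome(Genome("g", "GGCC"),
                               toyAnn(Genome("g", "GGCC"), starts = 1,
                                      ends = 2))$gc_percent, 100)
  s <- randSeq(1000, seed = 10)
  g <- Genome("g", s)
  ## two-exon cis gene: exons 101-160 and 201-260, intron 161-200 (40 bp)
  ann <- toyAnn(g, starts = c(101, 201), ends = c(160, 260), coding = c(1, 2),
                gene = c("x", "x"))
  ci <- cisIntronStats(ann)
  expect_identical(ci$n_introns, 1L)
  expect_identical(ci$total_bp, 40L)
  sm <- summarizeGenome(g, ann)
  f <- sm$features
  expect_equal(f$total_bp[f$category == "protein coding"], 120)
  expect_equal(f$percent[f$category == "protein coding"],
               roundHalfUp(100 * 120 / 1000, 1))
  expect_equal(f$total_bp[f$category == "cis-spliced introns"], 40)
})

test_that("FASTA round trip preserves sequence bytes and topology", {
  tmp <- tempfile(fileext = ".fasta")
  g1 <- Genome("alpha", "acgtacgtacgt", topology = "circular")
  g2 <- Genome("beta", randSeq(150, seed = 11))
  writeGenomeFasta(list(g1, g2), tmp)
  back <- readGenomeFasta(tmp)
  expect_length(back, 2)
  expect_identical(genomeId(back[[1]]), "alpha")
  expect_identical(genomeString(back[[1]]), "ACGTACGTACGT")  # case-folded
  expect_identical(topology(back[[1]]), "circular")
  expect_identical(topology(back[[2]]), "linear")
  expect_identical(genomeString(back[[2]]), genomeString(g2))

  empty <- tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(readGenomeFasta(empty), "empty|read")
  expect_error(readGenomeFasta(tempfile()), "no such file")
})

test_that("GFF3 round trip preserves gene models and coding order", {
  b <- smallBundle(21)
  tmp <- tempfile(fileext = ".gff3")
  writeAnnotationGff(b$mt_ann, tmp)
  back <- readAnnotationGff(tmp, b$mt)
  expect_setequal(genes(back)$gene_id, genes(b$mt_ann)$gene_id)
  for (gid in genes(b$mt_ann)$gene_id)
    expect_identical(spliceCds(b$mt, back, gid),
                     spliceCds(b$mt, b$mt_ann, gid), info = gid)
  ## trans-spliced flag survives
  expect_identical(genes(back)$trans_spliced[genes(back)$gene_id == "nad1"],
                   TRUE)
})

test_that("annotation validity rejects malformed gene models", {
  g <- Genome("g", randSeq(100, seed = 12))
  expect_error(toyAnn(g, starts = 50, ends = 150), "outside")
  expect_error(toyAnn(g, starts = c(10, 15), ends = c(20, 25),
                      coding = c(1, 2), gene = c("a", "a")), "overlap")
  expect_error(toyAnn(g, strand = c("+", "-"), starts = c(10, 40),
                      ends = c(20, 50), coding = c(1, 2),
                      gene = c("a", "a")), "strand")
})
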