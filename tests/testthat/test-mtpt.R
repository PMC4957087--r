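test_that("local search finds identical sequences and rejects unrelated ones", {
  s <- randSeq(1000, seed = 91)
  h <- localSearch(s, s)
  expect_gte(nrow(h), 1)
  top <- h[which.max(h$score), ]
  expect_identical(c(top$q_start, top$q_end), c(1L, 1000L))
  expect_equal(top$identity, 1)
  expect_identical(top$strand, "+")

  ## unrelated random pair at the default thresholds: no hits
  h0 <- localSearch(randSeq(5000, seed = 92), randSeq(5000, seed = 93))
  expect_identical(nrow(h0), 0L)

  ## a fully N-masked query can never hit
  hN <- localSearch(strrep("N", 500), s)
  expect_identical(nrow(hN), 0L)

  ## reverse-complement copy is found on the minus strand with correct
  ## subject coordinates
  frag <- substr(s, 201, 500)
  sub <- paste0(randSeq(300, seed = 94), revcomp(frag), randSeq(300, seed = 95))
  hm <- localSearch(frag, sub, min_identity = 0.9)
  expect_gte(nrow(hm), 1)
  expect_identical(hm$strand[1], "-")
  expect_identical(substr(sub, hm$s_start[1], hm$s_end[1]), revcomp(frag))
})

test_that("top local-search score equals exhaustive Smith-Waterman on short strings", {
  set.seed(96)
  for (i in 1:12) {
    q <- randSeq(sample(20:50, 1))
    s <- randSeq(sample(20:50, 1))
    w <- randSeq(15)
    q <- paste0(substr(q, 1, 10), w, substr(q, 26, nchar(q)))
    s <- paste0(substr(s, 1, 5), w, substr(s, 21, nchar(s)))
    h <- localSearch(q, s, min_identity = 0, max_evalue = Inf)
    oracle <- max(swOracleScore(q, s), swOracleScore(q, revcomp(s)))
    expect_gte(nrow(h), 1)
    expect_equal(max(h$score), oracle, info = paste("case", i))
  }
})

test_that("planted chloroplast fragments are recovered with near-exact boundaries", {
  b <- simulateBundle(PipelineConfig(rngSeed = 97))
  fr <- findCpInsertions(b$mt, b$mt_ann, b$cp, b$cp_ann, b$config)
  tr <- b$truth$fragments
  expect_identical(nrow(fr), nrow(tr))
  for (i in seq_len(nrow(tr))) {
    j <- which.min(abs(fr$mt_start - tr$mt_start[i]))
    expect_lte(abs(fr$mt_start[j] - tr$mt_start[i]), 5)
    expect_lte(abs(fr$mt_end[j] - tr$mt_end[i]), 5)
    expect_identical(fr$strand[j], tr$strand[i])
  }
  ## numbering follows decreasing length
  expect_identical(fr$no, seq_len(nrow(fr)))
  expect_true(all(diff(fr$length) <= 0))

  ## masking soundness: no fragment overlaps a masked gene exon
  ex <- exons(b$mt_ann)
  keep <- genes(b$mt_ann)$gene_id[genes(b$mt_ann)$category %in%
                                    c("protein", "tRNA", "rRNA")]
  masked <- IRanges::reduce(IRanges::ranges(ex[S4Vectors::mcols(ex)$gene_id
                                               %in% keep]))
  frIr <- IRanges::IRanges(fr$mt_start, fr$mt_end)
  expect_identical(length(IRanges::findOverlaps(frIr, masked)), 0L)

  ## the pinned fragment contains the chloroplast tRNA gene, intact
  expect_true(any(grepl("trnN(GTT)(intact)", fr$genes_contained, fixed = TRUE)))

  ## monotonicity: stricter thresholds never add fragments
  stricter <- PipelineConfig(mtptMinIdentity = 0.9, mtptMaxEvalue = 1e-20,
                             rngSeed = 97)
  fr2 <- findCpInsertions(b$mt, b$mt_ann, b$cp, b$cp_ann, stricter)
  expect_lte(nrow(fr2), nrow(fr))

  ## diverged fragments at 5% are still all recovered (>= 54 bp floor)
  b5 <- simulateBundle(PipelineConfig(rngSeed = 98), divergence = 0.05)
  fr5 <- findCpInsertions(b5$mt, b5$mt_ann, b5$cp, b5$cp_ann, b5$config)
  expect_identical(nrow(fr5), nrow(b5$truth$fragments))
})

test_that("an unannotated genome triggers a loud unmasked-search warning", {
  b <- smallBundle(99)
  expect_warning(findCpInsertions(b$mt, NULL, b$cp, b$cp_ann, b$config),
                 "UNMASKED")
})

test_that("homolog presence applies the identity and coverage floors", {
  b <- smallBundle(100)
  fr <- findCpInsertions(b$mt, b$mt_ann, b$cp, b$cp_ann, b$config)
  expect_gt(nrow(fr), 0)
  fseq <- substr(genomeString(b$mt), fr$mt_start[1], fr$mt_end[1])
  pad <- function(x) paste0(randSeq(2000, seed = 101), x,
                            randSeq(2000, seed = 102))
  ## verbatim copy: present with identity and coverage 1
  full <- Genome("full", pad(fseq))
  ## ~75% identity copy: below the 80% identity floor
  ch <- strsplit(fseq, "")[[1]]
  set.seed(103)
  idx <- sample(seq_along(ch), round(0.25 * length(ch)))
  for (p in idx) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  diverged <- Genome("diverged", pad(paste(ch, collapse = "")))
  ## half the fragment: coverage 0.5 at identity 1
  half <- Genome("half", pad(substr(fseq, 1, nchar(fseq) %/% 2)))
  hp <- findHomologs(fr[1, ], b$mt,
                     list(full = full, diverged = diverged, half = half),
                     b$config)
  expect_identical(hp$present[hp$species == "full"], TRUE)
  expect_equal(hp$best_identity[hp$species == "full"], 1)
  expect_gte(hp$best_coverage[hp$species == "full"], 1)
  expect_identical(hp$present[hp$species == "diverged"], FALSE)
  expect_identical(hp$present[hp$species == "half"], FALSE)
  expect_lte(hp$best_coverage[hp$species == "half"], 0.6)

  ## empty genome list gives an empty presence map
  expect_identical(nrow(findHomologs(fr, b$mt, list(), b$config)), 0L)
})

test_that("the published insertion table totals are reproduced", {
  tab <- lotusFragmentTable()
  expect_identical(nrow(tab), 19L)
  expect_identical(sum(tab$length), 8256L)
  expect_equal(percentOfGenome(sum(tab$length), 524797L), 1.6)
  ## positions are consistent with the printed lengths
  expect_identical(tab$end - tab$start + 1L, tab$length)
  expect_identical(range(tab$length), c(54L, 1998L))
})
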