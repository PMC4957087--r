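test_that("generation is fully deterministic under a fixed seed", {
  a <- generateMtGenome(PipelineConfig(rngSeed = 1))
  b <- generateMtGenome(PipelineConfig(rngSeed = 1))
  expect_identical(genomeString(a$genome), genomeString(b$genome))
  expect_identical(genes(a$ann), genes(b$ann))
  expect_identical(a$truth$gene_cds, b$truth$gene_cds)

  b1 <- smallBundle(5); b2 <- smallBundle(5)
  expect_identical(genomeString(b1$mt), genomeString(b2$mt))
  expect_identical(b1$cdna, b2$cdna)
  expect_identical(b1$truth$edits, b2$truth$edits)
})

test_that("generated gene models satisfy their structural invariants", {
  mtb <- generateMtGenome(PipelineConfig(rngSeed = 3), n_genes = 5L,
                          genome_len = 15000L)
  expect_identical(nrow(genes(mtb$ann)), 5L)
  expect_true(validObject(mtb$ann))
  expect_identical(topology(mtb$genome), "circular")

  g <- genes(mtb$ann)
  expect_true(any(g$trans_spliced))                      # trans-spliced gene
  expect_true(any(grepl("-1$", g$name)) && any(grepl("-2$", g$name)))
  nExons <- table(S4Vectors::mcols(exons(mtb$ann))$gene_id)
  expect_true(any(nExons[g$gene_id[!g$trans_spliced]] > 1))  # cis multi-exon

  ## both strands used somewhere (property of the default generator scale)
  full <- generateMtGenome(PipelineConfig(rngSeed = 3))
  expect_setequal(unique(as.character(GenomicRanges::strand(exons(full$ann)))),
                  c("+", "-"))

  ## every planted protein CDS translates cleanly: ATG start, single
  ## terminal stop, no internal stops (independent translation oracle)
  for (gid in g$gene_id[g$category == "protein"]) {
    cds <- mtb$truth$gene_cds[[gid]]
    expect_identical(nchar(cds) %% 3L, 0L)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    expect_identical(substr(aa, 1, 1), "M")
    expect_identical(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("*", substr(aa, 1, nchar(aa) - 1), fixed = TRUE))
  }
  expect_error(generateMtGenome(PipelineConfig(rngSeed = 1), n_genes = 12,
                                genome_len = 4000), "infeasible")
})

test_that("cDNA generation applies exactly the planted substitutions", {
  mtb <- generateMtGenome(PipelineConfig(rngSeed = 4))
  ## no edits, no noise: cDNA identical to spliced CDS
  cd0 <- generateCdna(mtb$genome, mtb$ann, NULL, seed = 1)
  for (gid in names(cd0$cdna))
    expect_identical(cd0$cdna[[gid]], spliceCds(mtb$genome, mtb$ann, gid))

  ## a single C-to-U edit changes exactly one position, C -> T
  cds <- mtb$truth$gene_cds[["atp9"]]
  cpos <- which(strsplit(cds, "")[[1]] == "C")[3]
  ed <- data.frame(gene_id = "atp9", cds_pos = cpos, direction = "C2U")
  cd1 <- generateCdna(mtb$genome, mtb$ann, ed, seed = 1)
  diff <- which(strsplit(cd1$cdna[["atp9"]], "")[[1]] != strsplit(cds, "")[[1]])
  expect_identical(diff, cpos)
  expect_identical(substr(cd1$cdna[["atp9"]], cpos, cpos), "T")

  ## editing a base that cannot move in the stated direction is an error
  tpos <- which(strsplit(cds, "")[[1]] == "T")[1]
  bad <- data.frame(gene_id = "atp9", cds_pos = tpos, direction = "C2U")
  expect_error(generateCdna(mtb$genome, mtb$ann, bad, seed = 1), "wants C")
})

test_that("planted chloroplast fragments are verbatim copies with guarded flanks", {
  cpb <- generateCpGenome(seed = 31)
  mtb <- generateMtGenome(PipelineConfig(rngSeed = 31))
  fr <- plantCpFragments(mtb$genome, mtb$ann, cpb$genome,
                         lengths = c(1998L, 500L, 54L), divergence = 0,
                         seed = 31)
  tr <- fr$truth
  expect_identical(sort(tr$length), sort(c(1998L, 500L, 54L)))
  for (i in seq_len(nrow(tr))) {
    mtSeg <- substr(genomeString(fr$genome), tr$mt_start[i], tr$mt_end[i])
    cpSeg <- substr(genomeString(cpb$genome), tr$cp_start[i], tr$cp_end[i])
    if (tr$strand[i] == "-") cpSeg <- revcomp(cpSeg)
    expect_identical(mtSeg, cpSeg)
  }

  ## divergence 0.1: observed mismatch fraction within 3 sigma of binomial
  fr2 <- plantCpFragments(mtb$genome, mtb$ann, cpb$genome,
                          lengths = 2000L, divergence = 0.1, seed = 32)
  t2 <- fr2$truth
  mtSeg <- substr(genomeString(fr2$genome), t2$mt_start, t2$mt_end)
  cpSeg <- substr(genomeString(cpb$genome), t2$cp_start, t2$cp_end)
  if (t2$strand == "-") cpSeg <- revcomp(cpSeg)
  mm <- mean(strsplit(mtSeg, "")[[1]] != strsplit(cpSeg, "")[[1]])
  ## substituted bases are drawn uniformly from the three others, so the
  ## realized mismatch rate estimates the divergence itself
  expect_lt(abs(mm - 0.1), 3 * sqrt(0.1 * 0.9 / 2000))
})

test_that("planted repeats and SSRs are verbatim at their recorded loci", {
  mtb <- generateMtGenome(PipelineConfig(rngSeed = 33))
  rs <- plantRepeatsAndSsrs(mtb$genome, mtb$ann,
                            repeat_spec = data.frame(
                              kind = c("direct", "inverted"),
                              length = c(600L, 700L)),
                            ssr_spec = data.frame(motif = "AT", n_units = 5L),
                            seed = 33)
  s <- genomeString(rs$genome)
  tr <- rs$truth$repeats
  dr <- tr[tr$kind == "direct", ]
  expect_identical(substr(s, dr$start_a, dr$end_a),
                   substr(s, dr$start_b, dr$end_b))
  ir <- tr[tr$kind == "inverted", ]
  expect_identical(substr(s, ir$start_b, ir$end_b),
                   revcomp(substr(s, ir$start_a, ir$end_a)))
  ssr <- rs$truth$ssrs
  expect_identical(substr(s, ssr$start, ssr$end), "ATATATATAT")
})

test_that("bundle truth is re-derivable from the emitted files alone", {
  b <- smallBundle(34)
  d <- tempfile()
  writeBundle(b, d)
  expect_setequal(list.files(d), c("mt.fasta", "mt.gff3", "cp.fasta",
                                   "cp.gff3", "cdna.fasta", "truth.json"))
  mt <- readGenomeFasta(file.path(d, "mt.fasta"))[[1]]
  truth <- jsonlite::read_json(file.path(d, "truth.json"),
                               simplifyVector = TRUE)
  s <- genomeString(mt)
  for (i in seq_len(nrow(truth$ssrs)))
    expect_identical(substr(s, truth$ssrs$start[i], truth$ssrs$end[i]),
                     strrep(truth$ssrs$motif[i], truth$ssrs$n_units[i]))
  cp <- readGenomeFasta(file.path(d, "cp.fasta"))[[1]]
  fr <- truth$fragments
  for (i in seq_len(nrow(fr))) {
    cpSeg <- substr(genomeString(cp), fr$cp_start[i], fr$cp_end[i])
    if (fr$strand[i] == "-") cpSeg <- revcomp(cpSeg)
    expect_identical(substr(s, fr$mt_start[i], fr$mt_end[i]), cpSeg)
  }
})
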