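test_that("DNA/cDNA global alignment is gap-free on colinear inputs", {
  s <- randSeq(90, seed = 41)
  a <- alignDnaCdna(s, s)
  expect_identical(a$n_mismatch, 0L)
  expect_false(grepl("-", a$dna, fixed = TRUE))

  ch <- strsplit(s, "")[[1]]
  ch[40] <- setdiff(c("A", "C", "G", "T"), ch[40])[1]
  a2 <- alignDnaCdna(s, paste(ch, collapse = ""))
  expect_identical(a2$n_mismatch, 1L)

  ## returned score never falls below the naive ungapped pairing
  set.seed(42)
  for (i in 1:10) {
    x <- randSeq(20); y <- randSeq(20)
    naive <- sum(ifelse(strsplit(x, "")[[1]] == strsplit(y, "")[[1]], 1, -1))
    expect_gte(alignDnaCdna(x, y)$score, naive)
  }
  expect_warning(alignDnaCdna(randSeq(100), randSeq(50)), "ratio")
})

test_that("edit calling emits only C<->T columns and full codon context", {
  cds <- paste(rep("GCTACGGATTCAGCAACGGATTCAGCATGA", 3), collapse = "")
  expect_identical(nrow(callEdits(cds, cds, "g")), 0L)

  ## planted C -> T at cds position 23 (codon 8, position 2)
  stopifnot(substr(cds, 23, 23) == "C")
  cdna <- cds; substr(cdna, 23, 23) <- "T"
  sites <- callEdits(cds, cdna, "g")
  expect_identical(nrow(sites), 1L)
  expect_identical(sites$direction, "C2U")
  expect_identical(sites$cds_pos, 23L)
  expect_identical(sites$codon_index, 8L)
  expect_identical(sites$codon_pos, 2L)
  expect_identical(sites$ref_codon, substr(cds, 22, 24))

  ## a G/A mismatch is a discrepancy, never an edit
  stopifnot(substr(cds, 7, 7) == "G")
  cdna2 <- cds; substr(cdna2, 7, 7) <- "A"
  s2 <- callEdits(cds, cdna2, "g")
  expect_identical(nrow(s2), 0L)
  d <- editDiscrepancies(s2)
  expect_identical(nrow(d), 1L)
  expect_identical(d$cds_pos, 7L)

  ## pseudogene edits are unpartitioned with no codon context
  s3 <- callEdits(cds, cdna, "ps", category = "pseudogene")
  expect_identical(s3$effect, "unpartitioned")
  expect_true(is.na(s3$codon_index))
})

test_that("edit-effect classification matches published examples and the exhaustive oracle", {
  ## the three published U-to-C cases
  r <- classifyEdit("GTG", 2, "U2C")
  expect_identical(c(r$edited_codon, r$ref_aa, r$edited_aa, r$effect),
                   c("GCG", "V", "A", "nonsynonymous"))
  r <- classifyEdit("TGC", 1, "U2C")
  expect_identical(c(r$edited_codon, r$ref_aa, r$edited_aa, r$effect),
                   c("CGC", "C", "R", "nonsynonymous"))
  r <- classifyEdit("TCT", 1, "U2C")
  expect_identical(c(r$edited_codon, r$ref_aa, r$edited_aa, r$effect),
                   c("CCT", "S", "P", "nonsynonymous"))
  ## third-position wobble
  expect_identical(classifyEdit("ACC", 3, "C2U")$effect, "synonymous")

  ## all 64 x 3 x 2 combinations: editable ones agree with the
  ## translate-and-compare oracle, the rest error out
  for (codon in names(Biostrings::GENETIC_CODE)) {
    for (pos in 1:3) {
      base <- substr(codon, pos, pos)
      for (dir in c("C2U", "U2C")) {
        editable <- (dir == "C2U" && base == "C") ||
                    (dir == "U2C" && base == "T")
        if (editable) {
          expect_identical(classifyEdit(codon, pos, dir)$effect,
                           effectOracle(codon, pos, dir),
                           info = paste(codon, pos, dir))
        } else {
          expect_error(classifyEdit(codon, pos, dir))
        }
      }
    }
  }
})

test_that("editing frequency reproduces the published per-gene rates", {
  ## the printed frequencies imply integer counts: round(freq * len / 100)
  expect_identical(round(7.111 * 225 / 100), 16)
  expect_identical(round(6.924 * 621 / 100), 43)
  expect_equal(editingFrequency(16, 225), 7.111)
  expect_equal(editingFrequency(43, 621), 6.924)
  expect_equal(editingFrequency(0, 300), 0)
  expect_error(editingFrequency(1, 0))
})

test_that("identical duplicated copies are reported once, divergent copies kept", {
  sites <- data.frame(gene_id = c("s-1", "s-1", "s-2", "s-2", "x-a", "x-b"),
                      cds_pos = c(5L, 9L, 5L, 9L, 3L, 3L),
                      direction = "C2U", stringsAsFactors = FALSE)
  genesDf <- data.frame(gene_id = c("s-1", "s-2", "x-a", "x-b"),
                        name = c("sdh3-1", "sdh3-2", "rpl2-a", "rpl2-b"),
                        category = "protein", origin = "native",
                        trans_spliced = FALSE, stringsAsFactors = FALSE)
  g <- Genome("g", randSeq(500, seed = 44))
  ex <- GenomicRanges::GRanges("g", IRanges::IRanges(c(10, 110, 210, 310),
                                                     c(40, 140, 240, 340)),
                               strand = "+")
  S4Vectors::mcols(ex)$gene_id <- genesDf$gene_id
  S4Vectors::mcols(ex)$coding_order <- 1L
  ann <- AnnotationSet(g, genesDf, ex)
  cds <- c("s-1" = "AAACCC", "s-2" = "AAACCC",
           "x-a" = "AAACCC", "x-b" = "AAACCG")
  out <- dedupeCopies(sites, ann, cds)
  expect_setequal(unique(out$gene_id), c("s-1", "x-a", "x-b"))
  expect_identical(nrow(out), 4L)
  ## no duplicates -> unchanged
  out2 <- dedupeCopies(sites[5:6, ], ann, cds)
  expect_identical(nrow(out2), 2L)
})

test_that("nonsynonymous share uses both labelled denominators", {
  ns <- nonsynShare(612, 58, 30)
  expect_identical(ns$total, 700)
  expect_equal(ns$pct_of_all, 87)
  expect_equal(ns$pct_of_partitioned, roundHalfUp(100 * 612 / 670, 0))
})

test_that("cross-species edit comparison matches by alignment column and is symmetric", {
  cds <- randSeq(30, seed = 45)
  a <- data.frame(gene_id = "g", cds_pos = c(4L, 10L), direction = "C2U")
  b <- data.frame(gene_id = "g", cds_pos = c(10L, 13L), direction = "C2U")
  r <- compareEditingSets(a, c(g = cds), b, c(g = cds))
  expect_identical(r$n_shared, 1L)
  expect_identical(r$n_unique_a, 1L)
  expect_identical(r$n_unique_b, 1L)

  ## species against itself: everything shared
  self <- compareEditingSets(a, c(g = cds), a, c(g = cds))
  expect_identical(self$n_shared, 2L)
  expect_identical(self$n_unique_a + self$n_unique_b, 0L)

  ## disjoint edit positions on identical CDSs share nothing
  dis <- compareEditingSets(a, c(g = cds),
                            data.frame(gene_id = "g", cds_pos = c(2L, 20L),
                                       direction = "C2U"), c(g = cds))
  expect_identical(dis$n_shared, 0L)

  ## symmetry: swapping species swaps the unique counts
  sw <- compareEditingSets(b, c(g = cds), a, c(g = cds))
  expect_identical(sw$n_shared, r$n_shared)
  expect_identical(sw$n_unique_a, r$n_unique_b)
  expect_identical(sw$n_unique_b, r$n_unique_a)

  ## a gene present in only one species is excluded and listed
  r2 <- compareEditingSets(a, c(g = cds, h = cds), b, c(g = cds))
  expect_identical(r2$excluded_genes, "h")
})

test_that("edit calls stay exact under substitution noise", {
  for (seed in c(61, 62)) {
    b <- smallBundle(seed, noise_rate = 0.005)
    truthAll <- b$truth$edits_all_copies
    nz <- b$truth$noise
    noiseKey <- paste(nz$gene_id, nz$cds_pos)
    gdf <- genes(b$mt_ann)
    for (gid in intersect(gdf$gene_id[gdf$category %in%
                                        c("protein", "pseudogene")],
                          names(b$cdna))) {
      cds <- spliceCds(b$mt, b$mt_ann, gid)
      sites <- callEdits(cds, b$cdna[[gid]], gid,
                         category = gdf$category[gdf$gene_id == gid])
      calledKey <- paste(sites$gene_id, sites$cds_pos, sites$direction)
      tg <- truthAll[truthAll$gene_id == gid, , drop = FALSE]
      ## recall: every planted edit is called unless noise hit its position
      for (i in seq_len(nrow(tg))) {
        k <- paste(tg$gene_id[i], tg$cds_pos[i], tg$direction[i])
        if (!(paste(tg$gene_id[i], tg$cds_pos[i]) %in% noiseKey))
          expect_true(k %in% calledKey, info = k)
      }
      ## precision: every unplanted call is a noise substitution that made
      ## a C<->T column; non-C/T noise is never called an edit
      truthKey <- paste(tg$gene_id, tg$cds_pos, tg$direction)
      extra <- sites[!(calledKey %in% truthKey), , drop = FALSE]
      for (i in seq_len(nrow(extra))) {
        hit <- nz[nz$gene_id == gid & nz$cds_pos == extra$cds_pos[i], ,
                  drop = FALSE]
        expect_identical(nrow(hit), 1L)
        expect_true((hit$from == "C" && hit$to == "T") ||
                      (hit$from == "T" && hit$to == "C"))
      }
    }
  }
})
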