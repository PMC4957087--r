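## Stage runner: one entry point per analysis stage plus an end-to-end run,
## with a JSON manifest (config snapshot, input digests, row counts, seed)
## so that identical manifests reproduce byte-identical TSV outputs.

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.stageError <- function(class, msg) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = NULL)))
}

.needInputs <- function(inputs, keys, stage) {
  miss <- setdiff(keys, names(inputs))
  missFile <- keys[vapply(keys, function(k)
    !is.null(inputs[[k]]) && !file.exists(inputs[[k]]), logical(1))]
  if (length(miss) || length(missFile))
    .stageError("mitoscan_missing_input",
                paste0("stage '", stage, "' missing input(s): ",
                       paste(unique(c(miss, missFile)), collapse = ", ")))
}

.KNOWN_STAGES <- c("simulate", "summarize", "rscu", "editing", "repeats",
                   "ssrs", "mtpt", "homologs", "synteny")

#' Run one analysis stage on files
#'
#' Thin file-level wrapper over the package's functions. Each stage reads
#' its inputs, writes its TSV outputs into `out_dir`, and records a
#' manifest (`<stage>.manifest.json`) holding the config snapshot, input
#' file digests, package version, per-output row counts and the seed, so a
#' re-run with an identical manifest reproduces byte-identical outputs.
#'
#' @param stage one of `simulate`, `summarize`, `rscu`, `editing`,
#'   `repeats`, `ssrs`, `mtpt`, `homologs`, `synteny`
#' @param inputs named list of input file paths; keys per stage: `mt`,
#'   `mt_gff`, `cp`, `cp_gff`, `cdna`, `fragments`, `genomes` (vector),
#'   `order_a`, `order_b`
#' @param config a [PipelineConfig-class]
#' @param out_dir output directory
#' @param seed integer seed (defaults to the config's)
#' @return list: `outputs` (paths), `manifest` (list), invisibly
#' @export
runStage <- function(stage, inputs = list(), config = PipelineConfig(),
                     out_dir = ".", seed = config@rngSeed) {
  if (!stage %in% .KNOWN_STAGES)
    .stageError("mitoscan_unknown_stage",
                paste0("unknown stage '", stage, "'; known: ",
                       paste(.KNOWN_STAGES, collapse = ", ")))
  if (!is(config, "PipelineConfig"))
    .stageError("mitoscan_config_violation", "config is not a PipelineConfig")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config
  cfg@rngSeed <- as.integer(seed)
  outputs <- character()
  counts <- list()
  readMt <- function() {
    .needInputs(inputs, c("mt"), stage)
    readGenomeFasta(inputs$mt)[[1]]
  }
  readAnn <- function(genome, key = "mt_gff") {
    .needInputs(inputs, key, stage)
    readAnnotationGff(inputs[[key]], genome)
  }
  if (stage == "simulate") {
    bundle <- simulateBundle(cfg)
    writeBundle(bundle, out_dir)
    outputs <- file.path(out_dir, c("mt.fasta", "mt.gff3", "cp.fasta",
                                    "cp.gff3", "cdna.fasta", "truth.json"))
    counts$genes <- nrow(genes(bundle$mt_ann))
    counts$edits <- nrow(bundle$truth$edits)
  } else if (stage == "summarize") {
    g <- readMt(); a <- readAnn(g)
    reps <- findLongRepeats(g, cfg@longRepeatMinLen, cfg@longRepeatMinIdentity)
    ssrs <- findSsrs(g, cfg@ssrMinUnits)
    sm <- summarizeGenome(g, a, repeats = reps, ssrs = ssrs)
    outputs <- writeGenomeSummaryTsv(sm, file.path(out_dir, "summary.tsv"))
    counts$features <- nrow(sm$features)
  } else if (stage == "rscu") {
    g <- readMt(); a <- readAnn(g)
    ids <- genes(a)$gene_id[genes(a)$category == "protein"]
    cds <- spliceAllCds(g, a, ids)
    cds <- cds[!duplicated(unname(cds))]   # duplicated copies counted once
    tab <- computeRscu(cds)
    outputs <- writeRscuTsv(tab, file.path(out_dir, "rscu.tsv"))
    counts$codons_counted <- sum(tab$count)
    counts$third_position_at_pct <- thirdPositionAT(cds)
  } else if (stage == "editing") {
    g <- readMt(); a <- readAnn(g)
    .needInputs(inputs, "cdna", stage)
    cdna <- readCdnaFasta(inputs$cdna)
    res <- runEditingAnalysis(g, a, cdna)
    o1 <- .writeTsv(res$sites, file.path(out_dir, "editing_sites.tsv"))
    o2 <- .writeTsv(res$profile, file.path(out_dir, "editing_profile.tsv"))
    outputs <- c(o1, o2)
    counts$sites <- nrow(res$sites)
  } else if (stage == "repeats") {
    g <- readMt()
    reps <- findLongRepeats(g, cfg@longRepeatMinLen, cfg@longRepeatMinIdentity)
    outputs <- .writeTsv(reps, file.path(out_dir, "repeats.tsv"))
    counts$repeats <- nrow(reps)
  } else if (stage == "ssrs") {
    g <- readMt()
    ssrs <- findSsrs(g, cfg@ssrMinUnits)
    o1 <- .writeTsv(ssrs, file.path(out_dir, "ssrs.tsv"))
    o2 <- writeSsrBed(ssrs, genomeId(g), file.path(out_dir, "ssrs.bed"))
    outputs <- c(o1, o2)
    counts$ssrs <- nrow(ssrs)
  } else if (stage == "mtpt") {
    g <- readMt(); a <- readAnn(g)
    .needInputs(inputs, "cp", stage)
    cp <- readGenomeFasta(inputs$cp)[[1]]
    cpAnn <- if (!is.null(inputs$cp_gff)) readAnn(cp, "cp_gff") else NULL
    fr <- findCpInsertions(g, a, cp, cpAnn, cfg)
    outputs <- .writeTsv(fr, file.path(out_dir, "cp_fragments.tsv"))
    counts$fragments <- nrow(fr)
    counts$fragment_bp <- sum(fr$length)
  } else if (stage == "homologs") {
    g <- readMt()
    .needInputs(inputs, c("fragments", "genomes"), stage)
    fr <- utils::read.delim(inputs$fragments)
    gens <- unlist(lapply(inputs$genomes, readGenomeFasta), recursive = FALSE)
    names(gens) <- vapply(gens, genomeId, character(1))
    hp <- findHomologs(fr, g, gens, cfg)
    outputs <- .writeTsv(hp, file.path(out_dir, "homolog_presence.tsv"))
    counts$records <- nrow(hp)
  } else if (stage == "synteny") {
    .needInputs(inputs, c("order_a", "order_b"), stage)
    readOrder <- function(p) {
      df <- utils::read.delim(p)
      geneOrderFromNames(df$name, df$strand)
    }
    cl <- findClusters(readOrder(inputs$order_a), readOrder(inputs$order_b))
    outputs <- .writeTsv(cl, file.path(out_dir, "clusters.tsv"))
    counts$clusters <- nrow(cl)
  }
  digests <- vapply(unlist(inputs, use.names = FALSE), function(p)
    unname(tools::md5sum(p)), character(1))
  manifest <- list(stage = stage,
                   tool_version = as.character(utils::packageVersion("mitoscan")),
                   config = configAsList(cfg),
                   inputs = as.list(digests),
                   outputs = basename(outputs),
                   row_counts = counts,
                   rng_seed = cfg@rngSeed)
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0(stage, ".manifest.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(outputs = outputs, manifest = manifest))
}

#' Run every stage end-to-end on a simulated bundle
#'
#' Simulates a bundle into `out_dir/bundle` and runs all file-level stages
#' on it, collecting the per-stage manifests.
#'
#' @param config a [PipelineConfig-class]
#' @param out_dir output directory
#' @return named list of per-stage results, invisibly
#' @export
runPipeline <- function(config = PipelineConfig(), out_dir = ".") {
  bdir <- file.path(out_dir, "bundle")
  res <- list()
  res$simulate <- runStage("simulate", config = config, out_dir = bdir)
  inp <- list(mt = file.path(bdir, "mt.fasta"),
              mt_gff = file.path(bdir, "mt.gff3"),
              cp = file.path(bdir, "cp.fasta"),
              cp_gff = file.path(bdir, "cp.gff3"),
              cdna = file.path(bdir, "cdna.fasta"))
  for (st in c("summarize", "rscu", "editing", "repeats", "ssrs", "mtpt"))
    res[[st]] <- runStage(st, inputs = inp, config = config,
                          out_dir = out_dir)
  res$homologs <- runStage("homologs",
                           inputs = c(inp, list(
                             fragments = file.path(out_dir, "cp_fragments.tsv"),
                             genomes = file.path(bdir, "cp.fasta"))),
                           config = config, out_dir = out_dir)
  invisible(res)
}
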