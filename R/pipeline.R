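#' Default run configuration
#'
#' Materializes every pipeline default: the motif catalog, the bundled
#' synthetic flank fixture, classifier geometry (anchor K = 30 bp, edit
#' fraction 0.25, 1 bp minimum overhang), the pathogenic threshold (650)
#' and rare-motif cutoff (1%), and a three-sample simulation block with
#' mean core counts 600/790/870 emulating three expansion carriers. The
#' full configuration is echoed to the run manifest, and every stochastic
#' stage derives an explicit seed from `seed`.
#'
#' @param seed Base integer seed.
#' @param coverage Fold coverage per sample.
#' @param errorRate Per-base error rate (default 0.12, inside the CLR
#'   11--15% band).
#' @param readLength Read length model (see [simulateReads()]).
#' @return A named list (class `RunConfig`).
#' @export
defaultRunConfig <- function(seed = 1, coverage = 40, errorRate = 0.12,
                             readLength = list(type = "lognormal",
                                               meanlog = log(5000),
                                               sdlog = 0.5, min = 500)) {
  fl <- bundledFlanks()
  list(
    catalog = list(core = "GGCCTG",
                   variants = c("GGCTG", "GGCCCTG", "GGCCG", "GGCCTTG")),
    left_flank = fl$left, right_flank = fl$right,
    anchor_k = 30, max_edit_fraction = 0.25, min_tract_bp = 1,
    threshold = 650, rare_threshold_pct = 1.0, count_mode = "dp",
    n_native = 4, n_insert = 1000,
    samples = list(list(id = "S600", mean_core = 600),
                   list(id = "S790", mean_core = 790),
                   list(id = "S870", mean_core = 870)),
    jitter_sd = 50, interruption_fraction = 0.05, variant_weights = NULL,
    coverage = coverage, read_length = readLength,
    error_rate = errorRate,
    error_mix = c(sub = 0.25, ins = 0.45, del = 0.30),
    strand_fraction = 0.5, waterfall_row_width = 50,
    seed = as.integer(seed), reads_fastq = NULL, truth_tsv = NULL)
}

#' Bundled synthetic flank fixture
#'
#' Seed-fixed synthetic 300 bp flanks shipped with the package
#' (`inst/extdata/flanks_synthetic.fa`). They stand in for the unique
#' sequence bordering a real repeat locus; extracting real flanks from a
#' reference genome is a documented recipe, not a build dependency.
#'
#' @return `list(left =, right =)` of DNA strings.
#' @export
bundledFlanks <- function() {
  path <- system.file("extdata", "flanks_synthetic.fa",
                      package = "RepeatSpan")
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  list(left = as.character(x[["left"]]), right = as.character(x[["right"]]))
}

#' Read a run configuration from YAML
#'
#' Unset keys fall back to [defaultRunConfig()]; `overrides` (a named
#' list) wins over the file.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides Named list of final overrides.
#' @return Validated config list.
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
  cfg <- defaultRunConfig()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    cfg[names(user)] <- user
  }
  cfg[names(overrides)] <- overrides
  validateRunConfig(cfg)
}

#' @rdname readRunConfig
#' @param cfg Config list to validate.
#' @export
validateRunConfig <- function(cfg) {
  stopifnot(is.list(cfg$samples), length(cfg$samples) >= 1)
  if (cfg$error_rate < 0 || cfg$error_rate >= 0.5)
    stop("error_rate must lie in [0, 0.5)")
  if (abs(sum(unlist(cfg$error_mix)) - 1) > 1e-6)
    stop("error_mix must sum to 1")
  if (is.null(cfg$seed)) stop("config must carry an explicit seed")
  cfg$seed <- as.integer(cfg$seed)
  assertDna(cfg$left_flank, "left_flank")
  assertDna(cfg$right_flank, "right_flank")
  cfg$catalogObj <- MotifCatalog(cfg$catalog$core,
                                 unlist(cfg$catalog$variants))
  cfg
}

.sampleSeed <- function(base, i) (as.integer(base) + 1000L * i) %% .Machine$integer.max

#' Run the full characterization pipeline
#'
#' Executes simulate (skipped when `config$reads_fastq` supplies real
#' reads) -> build-ref -> classify -> quantify -> motifs -> report,
#' writing every stage product under `outDir`: FASTQ + truth TSV per
#' simulated sample, the native/fake reference pair (FASTA + BED), per-read
#' classification TSVs and tract FASTAs, the per-sample summary table
#' (TSV + JSON), motif ratio and token tables, waterfall SVGs of the
#' highest-repeat full-length read per sample, distribution plots and an
#' HTML index, plus a `manifest.json` echoing the full configuration.
#' Identical config and seeds give byte-identical tables.
#'
#' @param config Config list from [defaultRunConfig()]/[readRunConfig()].
#' @param outDir Output directory (created).
#' @param stages Character subset of
#'   `c("simulate", "build-ref", "classify", "quantify", "motifs",
#'   "report")`; earlier stage outputs must exist when a stage is re-run
#'   in isolation.
#' @return Invisibly, a list with the per-sample summary data.frame and
#'   the main output paths.
#' @export
runPipeline <- function(config, outDir,
                        stages = c("simulate", "build-ref", "classify",
                                   "quantify", "motifs", "report")) {
  config <- validateRunConfig(config)
  catalog <- config$catalogObj
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  for (d in c("reads", "ref", "classify", "quantify", "motifs", "report"))
    dir.create(file.path(outDir, d), showWarnings = FALSE)
  manifest <- config[setdiff(names(config), "catalogObj")]
  manifest$package_version <- as.character(utils::packageVersion("RepeatSpan"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  sampleIds <- vapply(config$samples, `[[`, character(1), "id")

  if ("simulate" %in% stages && is.null(config$reads_fastq)) {
    for (i in seq_along(config$samples)) {
      s <- config$samples[[i]]
      reads <- simulateSample(
        sampleId = s$id, meanCore = s$mean_core,
        jitterSd = config$jitter_sd,
        interruptionFraction = config$interruption_fraction,
        variantWeights = config$variant_weights, catalog = catalog,
        leftFlank = config$left_flank, rightFlank = config$right_flank,
        coverage = config$coverage, readLength = config$read_length,
        errorRate = config$error_rate, errorMix = config$error_mix,
        strandFraction = config$strand_fraction,
        anchorK = config$anchor_k,
        maxEditFraction = config$max_edit_fraction,
        minTractBp = config$min_tract_bp,
        seed = .sampleSeed(config$seed, i))
      writeReadsFastq(reads, file.path(outDir, "reads",
                                       paste0(s$id, ".fastq")))
      writeTruthTsv(reads, file.path(outDir, "reads",
                                     paste0(s$id, ".truth.tsv")))
    }
  }

  if ("build-ref" %in% stages) {
    pair <- buildReferencePair(config$left_flank, config$right_flank,
                               core = coreMotif(catalog),
                               nNative = config$n_native,
                               nInsert = config$n_insert,
                               anchorK = config$anchor_k)
    writeReferencePair(pair, file.path(outDir, "ref"))
  }

  if ("classify" %in% stages) {
    if (!is.null(config$reads_fastq)) {
      ## user-supplied reads: one read set, treated as one sample
      if (!file.exists(config$reads_fastq))
        stop("reads file not found: ", config$reads_fastq)
      reads <- readReads(config$reads_fastq)
      cl <- classifyReads(reads, config$left_flank, config$right_flank,
                          anchorK = config$anchor_k,
                          maxEditFraction = config$max_edit_fraction,
                          minTractBp = config$min_tract_bp,
                          sampleId = sampleIds[1L])
      writeClassifiedTsv(cl, file.path(outDir, "classify",
                                       paste0(sampleIds[1L], ".tsv")))
      writeTractFasta(cl, file.path(outDir, "classify",
                                    paste0(sampleIds[1L], ".tracts.fa")))
      sampleIds <- sampleIds[1L]
    } else {
      for (id in sampleIds) {
        fq <- file.path(outDir, "reads", paste0(id, ".fastq"))
        if (!file.exists(fq)) stop("missing stage input: ", fq)
        reads <- readReads(fq)
        cl <- classifyReads(reads, config$left_flank, config$right_flank,
                            anchorK = config$anchor_k,
                            maxEditFraction = config$max_edit_fraction,
                            minTractBp = config$min_tract_bp,
                            sampleId = id)
        writeClassifiedTsv(cl, file.path(outDir, "classify",
                                         paste0(id, ".tsv")))
        writeTractFasta(cl, file.path(outDir, "classify",
                                      paste0(id, ".tracts.fa")))
      }
    }
  }

  readClassified <- function(id) {
    tsv <- file.path(outDir, "classify", paste0(id, ".tsv"))
    fa <- file.path(outDir, "classify", paste0(id, ".tracts.fa"))
    if (!file.exists(tsv)) stop("missing stage input: ", tsv)
    cl <- read.delim(tsv, stringsAsFactors = FALSE, check.names = FALSE)
    cl$tract <- NA_character_
    if (file.size(fa) > 0) {
      tr <- Biostrings::readDNAStringSet(fa)
      ids <- sub("\\s.*$", "", names(tr))
      cl$tract[match(ids, cl$read_id)] <- as.character(tr)
    }
    cl
  }

  summary <- NULL
  if ("quantify" %in% stages) {
    summaries <- lapply(sampleIds, function(id)
      summarizeSample(readClassified(id), sampleId = id,
                      catalog = catalog, threshold = config$threshold,
                      countMode = config$count_mode))
    summary <- summarizeSamples(summaries)
    writeSummaryTsv(summary, file.path(outDir, "quantify", "summary.tsv"))
  }

  if ("motifs" %in% stages || "report" %in% stages) {
    allClassified <- do.call(rbind, lapply(sampleIds, readClassified))
    fullStats <- fullLengthStats(allClassified, catalog,
                                 countMode = config$count_mode)
    write.table(fullStats, file.path(outDir, "quantify",
                                     "full_length_stats.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    perSampleTok <- lapply(sampleIds, function(id) {
      cl <- allClassified[allClassified$sample_id == id &
                            allClassified$span_class %in%
                              c("full_dGGCCTGn", "full_dGGCCTGr"), ]
      lapply(cl$tract, tokenize, catalog = catalog)
    })
    names(perSampleTok) <- sampleIds

    allTok <- unlist(perSampleTok, use.names = FALSE)

    if ("motifs" %in% stages && length(allTok)) {
      for (id in sampleIds) {
        if (!length(perSampleTok[[id]])) next
        rt <- motifRatios(perSampleTok[[id]], scope = "pooled")
        writeMotifRatiosTsv(rt, file.path(outDir, "motifs",
                                          paste0(id, ".ratios.tsv")))
      }
      pooledAll <- motifRatios(allTok, scope = "pooled")
      writeMotifRatiosTsv(pooledAll,
                          file.path(outDir, "motifs", "pooled.ratios.tsv"))
      rare <- rareMotifLabels(pooledAll, config$rare_threshold_pct)
      writeLines(rare, file.path(outDir, "motifs", "rare_labels.txt"))
    }

    if ("report" %in% stages && length(allTok)) {
      pooledAll <- motifRatios(allTok, scope = "pooled")
      rare <- rareMotifLabels(pooledAll, config$rare_threshold_pct)
      ## waterfall of the highest-repeat full-length read per sample
      for (id in sampleIds) {
        st <- fullStats[fullStats$sample_id == id, ]
        if (!nrow(st)) next
        best <- st$read_id[which.max(st$core_count)]
        tr <- allClassified$tract[allClassified$read_id == best]
        renderWaterfall(tokenize(tr, catalog), catalog, rareLabels = rare,
                        rowWidth = config$waterfall_row_width,
                        title = paste0(id, " ", best),
                        file = file.path(outDir, "report",
                                         paste0(id, ".waterfall.svg")))
      }
      if (nrow(fullStats)) {
        plots <- plotDistributions(allClassified, fullStats)
        for (nm in names(plots))
          ggplot2::ggsave(file.path(outDir, "report",
                                    paste0(nm, ".png")), plots[[nm]],
                          width = 7, height = 4.5, dpi = 120)
      }
      writeRunReport(outDir)
    }
  }

  invisible(list(summary = summary, dir = outDir))
}
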