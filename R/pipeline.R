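# Workflow orchestration: configuration, the end-to-end pipeline and its
# output bundle. All intermediate artefacts are plain standard formats
# (FASTQ / SAM / TSV) re-ingestable by the stage that produced them.

#' Default run configuration
#'
#' @return named list of all tunable pipeline settings with their
#'   defaults: `qMin` 30, `minOverlap` 10, `maxMismatchFrac` 0.1,
#'   `maxMismatches` 7, `mapqMin` 0, `overlapOnly` TRUE, `dedup` TRUE,
#'   `alternative` "two.sided", `alpha` 0.05, `controlGroup` "control",
#'   `seed` 1.
#' @export
defaultConfig <- function() {
  list(qMin = 30, minOverlap = 10, maxMismatchFrac = 0.1,
       maxMismatches = 7, mapqMin = 0, overlapOnly = TRUE, dedup = TRUE,
       alternative = "two.sided", alpha = 0.05,
       controlGroup = "control", seed = 1, outputDir = NULL,
       reference = NULL, samples = NULL, catalogue = NULL)
}

#' Read a YAML run configuration
#'
#' @param path YAML file with keys as in [defaultConfig()]; `samples` is a
#'   list of records with `id`, `group` and either `fastq1`/`fastq2` or
#'   `sam`.
#' @return configuration list with defaults filled in.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  modifyList(defaultConfig(), cfg)
}

.validateConfig <- function(cfg) {
  if (is.null(cfg$reference)) stop("config: reference is required")
  if (is.null(cfg$samples) || !length(cfg$samples))
    stop("config: at least one sample is required")
  ids <- vapply(cfg$samples, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("config: duplicate sample ids")
  grp <- vapply(cfg$samples, `[[`, "", "group")
  if (!any(grp == cfg$controlGroup))
    stop("config: no sample in the control group '", cfg$controlGroup,
         "'")
  if (all(grp == cfg$controlGroup))
    stop("config: no non-control samples")
  for (s in cfg$samples) {
    paths <- c(s$fastq1, s$fastq2, s$sam)
    if (!length(paths)) stop("config: sample ", s$id, " has no input")
    miss <- paths[!file.exists(paths)]
    if (length(miss))
      stop("config: missing input for sample ", s$id, ": ",
           paste(miss, collapse = ", "))
  }
  invisible(cfg)
}

.log <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full mutation-frequency workflow
#'
#' Executes merge, alignment (or SAM ingest), duplicate removal, pileup
#' counting, frequency calculation, Dunnett testing against the control
#' group, background subtraction, spectrum construction and (when a
#' catalogue is configured) cosine comparison and hierarchical clustering.
#' Rerunning with the same inputs and seed is bit-identical.
#'
#' @param config configuration list (see [defaultConfig()]) or the path to
#'   a YAML file for [readRunConfig()].
#' @return invisible list: per-sample frequency tables, the Dunnett
#'   results per type, per-sample deltas, per-group spectra, clustering
#'   (if a catalogue was given) and output paths.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  cfg <- modifyList(defaultConfig(), config)
  .validateConfig(cfg)
  outDir <- cfg$outputDir
  logCon <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    logCon <- file(file.path(outDir, "run.log"), "w")
    on.exit(close(logCon))
  }
  .log(logCon, "popmutscan ", as.character(utils::packageVersion(
    "popmutscan")))
  for (k in c("qMin", "minOverlap", "maxMismatchFrac", "maxMismatches",
              "mapqMin", "overlapOnly", "dedup", "alternative", "alpha",
              "seed"))
    .log(logCon, "  ", k, " = ", cfg[[k]])
  set.seed(cfg$seed)
  genome <- if (methods::is(cfg$reference, "ReferenceGenome"))
    cfg$reference else loadReference(cfg$reference)
  idx <- if (nchar(genome@concat) > 5e4) genomeIndex(genome) else NULL
  mfts <- list()
  failures <- character()
  for (s in cfg$samples) {
    res <- tryCatch({
      if (!is.null(s$sam)) {
        aligned <- readSam(s$sam, genome, mapqMin = cfg$mapqMin)
      } else {
        pairs <- readFastqPairs(s$fastq1, s$fastq2)
        merged <- mergePairs(pairs, cfg$minOverlap, cfg$maxMismatchFrac)
        .log(logCon, "sample ", s$id, ": merged ", length(merged), "/",
             length(pairs), " pairs")
        if (!is.null(outDir)) {
          writeMergedFastq(merged, file.path(outDir,
                                             paste0(s$id, ".merged.fastq")))
        }
        aligned <- alignExact(merged, genome,
                              maxMismatches = cfg$maxMismatches,
                              method = if (is.null(idx)) "auto" else
                                "index", index = idx)
        if (!is.null(outDir))
          writeSam(aligned, genome, file.path(outDir,
                                              paste0(s$id, ".sam")))
      }
      if (cfg$dedup) aligned <- removeDuplicates(aligned)
      bcm <- buildBaseCounts(aligned, genome, qMin = cfg$qMin,
                             overlapOnly = cfg$overlapOnly)
      countSubstitutions(bcm, genome, sample = s$id, group = s$group,
                         dose = if (is.null(s$dose)) NA_real_ else s$dose)
    }, error = function(e) {
      .log(logCon, "sample ", s$id, " FAILED: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) failures <- c(failures, s$id) else
      mfts[[s$id]] <- res
  }
  if (length(failures))
    stop("sample(s) failed: ", paste(failures, collapse = ", "))
  groups <- vapply(cfg$samples, `[[`, "", "group")
  names(groups) <- vapply(cfg$samples, `[[`, "", "id")
  ctrl <- mfts[names(groups)[groups == cfg$controlGroup]]
  expoIds <- names(groups)[groups != cfg$controlGroup]
  deltas <- lapply(mfts[expoIds], subtractBackground, controls = ctrl)
  freq <- vapply(mfts, function(x) x@freq6, numeric(6))
  glabs <- setdiff(unique(groups), cfg$controlGroup)
  testable <- glabs[vapply(glabs, function(g) sum(groups == g) >= 2,
                           logical(1))]
  if (sum(groups == cfg$controlGroup) < 2) testable <- character()
  skipped <- setdiff(glabs, testable)
  if (length(skipped))
    .log(logCon, "skipping Dunnett for group(s) with < 2 replicates: ",
         paste(skipped, collapse = ", "))
  tests <- if (length(testable)) {
    lapply(setNames(SUB_TYPES, SUB_TYPES), function(t)
      dunnettTest(freq[t, groups == cfg$controlGroup],
                  lapply(setNames(testable, testable), function(g)
                    freq[t, groups == g]),
                  alternative = cfg$alternative))
  } else list()
  spectra <- list()
  for (g in glabs) {
    d96 <- rowMeans(vapply(deltas[names(groups)[groups == g &
                                                  names(groups) %in%
                                                  expoIds]],
                           function(d) d@delta96, numeric(96)))
    sp <- tryCatch(buildSpectrum(d96, name = g), error = function(e) NULL)
    if (!is.null(sp)) spectra[[g]] <- sp
  }
  clustering <- NULL; simset <- NULL
  if (!is.null(cfg$catalogue) && length(spectra)) {
    catalogue <- loadSignatureCatalogue(cfg$catalogue)
    simset <- spectrumSet(spectra, catalogue)
    clustering <- clusterSpectra(simset)
  }
  if (!is.null(outDir)) {
    writeFrequencyTables(mfts, file.path(outDir, "freq6.tsv"),
                         file.path(outDir, "freq96.tsv"))
    if (length(tests)) {
      dtab <- do.call(rbind, lapply(names(tests), function(t)
        cbind(type = t, tests[[t]]@table)))
      write.table(dtab, file.path(outDir, "dunnett.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    del6 <- do.call(rbind, lapply(deltas, function(d)
      cbind(data.frame(sample = d@sample),
            as.data.frame(as.list(d@delta6), check.names = FALSE))))
    write.table(del6, file.path(outDir, "delta6.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(simset)) {
      writeSimilarityMatrix(simset, file.path(outDir, "similarity.tsv"))
      writeNewick(clustering, file.path(outDir, "clustering.nwk"))
    }
    yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1)) &
                           names(cfg) != "reference"],
                     file.path(outDir, "config.yaml"))
  }
  .log(logCon, "done: ", length(mfts), " samples")
  invisible(list(frequencies = mfts, tests = tests, deltas = deltas,
                 spectra = spectra, clustering = clustering,
                 similarity = if (!is.null(simset))
                   1 - cosineDistances(simset) else NULL,
                 config = cfg))
}
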