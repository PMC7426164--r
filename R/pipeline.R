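## Pipeline stage drivers. Each run* function wraps one analysis stage,
## writes its primary outputs as TSV into `outDir`, and records a run
## manifest (JSON) so that a run can be reproduced: identical inputs and
## seed give byte-identical primary outputs for deterministic stages.
## A thin command-line wrapper over these functions ships in
## inst/scripts/ltsp-pipeline.R.

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Write a run manifest
#'
#' Records the subcommand, a digest of the resolved configuration, the
#' seed, the input paths and the package version as
#' `<outDir>/<subcommand>_manifest.json`.
#'
#' @param subcommand Stage name.
#' @param config List of resolved parameters.
#' @param inputPaths Character vector of input files.
#' @param outDir Output directory.
#' @param seed Integer seed or `NULL`.
#' @return Invisibly, the manifest path.
#' @export
writeRunManifest <- function(subcommand, config, inputPaths, outDir,
                             seed = NULL) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  manifest <- list(subcommand = subcommand,
                   config_hash = unname(tools::md5sum(tmp)),
                   seed = if (is.null(seed)) NA else seed,
                   input_paths = as.character(inputPaths),
                   version = as.character(utils::packageVersion("ltspRecovery")))
  path <- file.path(outDir, paste0(subcommand, "_manifest.json"))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path)
  invisible(path)
}

#' Growth-rate stage: rates and recovery summaries from a plate CSV
#'
#' Fits every well of the plate, averages the qualified wild-type wells
#' into the reference rate, and reports each well's rate and
#' percent-of-wild-type. When `sampleInfo` maps wells to recovery
#' trajectories (columns `sample_id`, `subject`, `cycle`), a per-subject
#' recovery summary at the given threshold is written as well.
#'
#' @param plateCsv Path to a plate-reader CSV (see [readPlateCsv()]).
#' @param wildtypeIds Character vector of well names holding the
#'   wild-type reference.
#' @param outDir Output directory (created if needed).
#' @param sampleInfo Optional data.frame mapping wells to `subject` and
#'   `cycle` for recovery summaries.
#' @param window,r2Min,odFloor Passed to [fitExponentialRate()].
#' @param threshold Recovery threshold in percent (default 90).
#' @return Invisibly, a list with the rates data.frame (`rates`) and, if
#'   computed, the recovery data.frame (`recovery`).
#' @export
runGrowth <- function(plateCsv, wildtypeIds, outDir, sampleInfo = NULL,
                      window = 5L, r2Min = 0.99, odFloor = 0.01,
                      threshold = 90) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  curves <- readPlateCsv(plateCsv)
  missing <- setdiff(wildtypeIds, names(curves))
  if (length(missing))
    stop("wild-type well(s) not present in plate: ",
         paste(missing, collapse = ", "))
  fits <- lapply(curves, fitExponentialRate, window = window,
                 r2Min = r2Min, odFloor = odFloor)
  wtFits <- fits[wildtypeIds]
  wtQual <- vapply(wtFits, isQualified, logical(1))
  if (!any(wtQual))
    stop("no wild-type well produced a qualified growth-rate estimate")
  wtRate <- mean(vapply(wtFits[wtQual], growthRate, numeric(1)))
  rates <- do.call(rbind, lapply(names(fits), function(id) {
    f <- fits[[id]]
    q <- isQualified(f)
    data.frame(sample_id = id,
               rate_per_min = if (q) growthRate(f) else NA_real_,
               window_start_min = if (q)
                 curves[[id]]@times[windowStart(f)] else NA_real_,
               r2 = if (q) windowR2(f) else NA_real_,
               relative_percent = if (q) 100 * growthRate(f) / wtRate
                                  else NA_real_,
               stringsAsFactors = FALSE)
  }))
  .writeTsv(rates, file.path(outDir, "rates.tsv"))
  out <- list(rates = rates)
  if (!is.null(sampleInfo)) {
    stopifnot(all(c("sample_id", "subject", "cycle") %in% names(sampleInfo)))
    merged <- merge(rates, sampleInfo, by = "sample_id")
    recovery <- do.call(rbind, lapply(split(merged, merged$subject),
                                      function(g) {
      g <- g[order(g$cycle), ]
      g <- g[!is.na(g$relative_percent), ]
      if (nrow(g) == 0L) return(NULL)
      s <- recoverySummary(g$cycle, g$relative_percent, threshold)
      data.frame(subject = g$subject[1L],
                 max_relative_rate = s$maxRelativeRate,
                 first_cycle_at_threshold = s$firstCycleAtThreshold,
                 stringsAsFactors = FALSE)
    }))
    rownames(recovery) <- NULL
    .writeTsv(recovery, file.path(outDir, "recovery.tsv"))
    out$recovery <- recovery
  }
  writeRunManifest("growth",
                   list(wildtypeIds = wildtypeIds, window = window,
                        r2Min = r2Min, odFloor = odFloor,
                        threshold = threshold),
                   plateCsv, outDir)
  invisible(out)
}

#' dN/dS stage: per-group mutation spectra from a mutation table
#'
#' Groups the rows of a mutation TSV (package dialect) by a column
#' (default `clone_id`), counts nonsynonymous and synonymous mutations
#' per group, and writes a table of totals, counts, dN/dS (`NA` where no
#' synonymous mutations were observed) and the chi-squared enrichment
#' p-value. Nonsense, frameshift, noncoding, intergenic and structural
#' mutations count toward the total but enter neither dN/dS class.
#'
#' @param mutationTsv Path to a mutation table (see
#'   [readMutationTable()]).
#' @param outDir Output directory.
#' @param sites A [SiteCounts-class]; defaults to the packaged E. coli
#'   K-12 codon-usage-derived counts.
#' @param grouping Column of the table to group by.
#' @return Invisibly, the results data.frame.
#' @export
runDnds <- function(mutationTsv, outDir,
                    sites = siteCountsFromCodonUsage(ecoliCodonUsage()),
                    grouping = "clone_id") {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  df <- utils::read.delim(mutationTsv, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("mutation table '", mutationTsv, "' is empty")
  if (!(grouping %in% names(df)))
    stop("grouping column '", grouping, "' not found in '", mutationTsv, "'")
  res <- do.call(rbind, lapply(split(df, df[[grouping]]), function(g) {
    nNs <- sum(g$mclass == "nonsynonymous")
    nSyn <- sum(g$mclass == "synonymous")
    total <- nrow(g)
    if (nNs + nSyn == 0) {
      warning("group '", g[[grouping]][1L],
              "' has no coding point mutations; reporting NA")
      return(data.frame(dataset = g[[grouping]][1L], total = total,
                        nonsynonymous = nNs, synonymous = nSyn,
                        dnds = NA_real_, chi2_p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    r <- dndsResult(nNs, nSyn, sites)
    data.frame(dataset = g[[grouping]][1L], total = total,
               nonsynonymous = nNs, synonymous = nSyn,
               dnds = dndsValue(r), chi2_p = pValue(r),
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  .writeTsv(res, file.path(outDir, "dnds.tsv"))
  writeRunManifest("dnds", list(grouping = grouping,
                                nsSites = nsSites(sites),
                                synSites = synSites(sites)),
                   mutationTsv, outDir)
  invisible(res)
}

#' Classification stage: RNAPC categories and recovery outcomes
#'
#' Writes the per-cycle RNAPC category frequency table for the clones of
#' a mutation TSV. When the table carries a `founder_id` column, also
#' writes per-descendant reversion/compensation outcome calls against the
#' named founder clones.
#'
#' @param mutationTsv Path to a mutation table (package TSV dialect),
#'   optionally with a `founder_id` column naming each descendant's
#'   founding clone (rows of founders themselves leave it empty).
#' @param outDir Output directory.
#' @param cfg An [anRnapcConfig()].
#' @return Invisibly, list with `frequencies` and, when lineage
#'   information is present, `outcomes`.
#' @export
runClassify <- function(mutationTsv, outDir, cfg = anRnapcConfig()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  clones <- readMutationTable(mutationTsv, "tsv")
  freq <- frequencyTable(clones, cfg)
  .writeTsv(freq, file.path(outDir, "rnapc_frequencies.tsv"))
  out <- list(frequencies = freq)
  raw <- utils::read.delim(mutationTsv, stringsAsFactors = FALSE,
                           colClasses = c(clone_id = "character"))
  if ("founder_id" %in% names(raw)) {
    raw$founder_id <- as.character(raw$founder_id)
    lineage <- unique(raw[, c("clone_id", "founder_id")])
    lineage <- lineage[!is.na(lineage$founder_id) &
                         nzchar(lineage$founder_id), , drop = FALSE]
    byId <- stats::setNames(clones, vapply(clones, cloneId, character(1)))
    unknown <- setdiff(lineage$founder_id, names(byId))
    if (length(unknown))
      stop("lineage references unknown founder(s): ",
           paste(unknown, collapse = ", "))
    outcomes <- data.frame(
      clone_id = lineage$clone_id, founder_id = lineage$founder_id,
      outcome = mapply(function(d, f)
        classifyOutcome(byId[[f]], byId[[d]], cfg),
        lineage$clone_id, lineage$founder_id),
      stringsAsFactors = FALSE)
    rownames(outcomes) <- NULL
    .writeTsv(outcomes, file.path(outDir, "outcomes.tsv"))
    out$outcomes <- outcomes
  }
  writeRunManifest("classify",
                   list(sites = cfg$sites, rnapcGenes = cfg$rnapcGenes),
                   mutationTsv, outDir)
  invisible(out)
}

#' Simulation stage: run the serial-dilution simulator from a YAML config
#'
#' The YAML file may define `config:` (fields of [simulationConfig()]),
#' `genotypes:` (a list of [genotypeSpecs()] rows with an added
#' `initialCount`), and optional `emit:` settings (`nClones`,
#' `odNoiseSd`). Writes `trajectory.tsv`, `mean_relative_rate.tsv`, a
#' clone table `clones.tsv` sampled from the final state, and a plate CSV
#' `plate.csv` of per-genotype growth curves.
#'
#' @param configYaml Path to the YAML configuration.
#' @param outDir Output directory.
#' @param seed Optional integer; overrides `config$seed`.
#' @return Invisibly, the [runExperiment()] result.
#' @export
runSimulate <- function(configYaml, outDir, seed = NULL) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  y <- yaml::read_yaml(configYaml)
  cfgArgs <- y$config
  if (!is.null(seed)) cfgArgs$seed <- seed
  cfg <- do.call(simulationConfig, cfgArgs)
  gts <- do.call(rbind, lapply(y$genotypes, function(g)
    data.frame(genotypeId = g$genotypeId, relativeRate = g$relativeRate,
               mutator = g$mutator %||% FALSE,
               carriesAnrnapc = g$carriesAnrnapc %||% FALSE,
               baseMutationLoad = g$baseMutationLoad %||% 0,
               initialCount = g$initialCount,
               stringsAsFactors = FALSE)))
  specs <- genotypeSpecs(gts$genotypeId, gts$relativeRate, gts$mutator,
                         gts$carriesAnrnapc, gts$baseMutationLoad)
  init <- PopulationState(stats::setNames(as.numeric(gts$initialCount),
                                          gts$genotypeId))
  res <- runExperiment(init, specs, cfg)
  .writeTsv(res$trajectory, file.path(outDir, "trajectory.tsv"))
  .writeTsv(res$meanRelativeRate, file.path(outDir, "mean_relative_rate.tsv"))
  nClones <- y$emit$nClones %||% 10L
  clones <- emitCloneSample(res$states[[length(res$states)]], res$specs,
                            nClones)
  writeMutationTable(clones, file.path(outDir, "clones.tsv"))
  curves <- emitOdCurves(res$specs, noiseSd = y$emit$odNoiseSd %||% 0.002)
  plate <- data.frame(time_min = curves[[1L]]@times)
  for (nm in names(curves)) plate[[nm]] <- curves[[nm]]@od
  utils::write.csv(plate, file.path(outDir, "plate.csv"), row.names = FALSE)
  writeRunManifest("simulate", c(unclass(cfg), list(genotypes = gts)),
                   configYaml, outDir, seed = cfg$seed)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Join stage outputs into one summary table
#'
#' Collects whatever stage outputs are present under `runDir`
#' (`rates.tsv`, `recovery.tsv`, `dnds.tsv`, `rnapc_frequencies.tsv`,
#' `outcomes.tsv`) and writes a long-format `summary.tsv` with columns
#' `stage`, `item`, `metric`, `value`.
#'
#' @param runDir Directory holding stage outputs.
#' @return Invisibly, the summary data.frame.
#' @export
runReport <- function(runDir) {
  long <- function(df, stage, itemCol) {
    num <- names(df)[vapply(df, is.numeric, logical(1))]
    do.call(rbind, lapply(num, function(cn)
      data.frame(stage = stage, item = as.character(df[[itemCol]]),
                 metric = cn, value = df[[cn]], stringsAsFactors = FALSE)))
  }
  pieces <- list()
  f <- function(p) file.path(runDir, p)
  if (file.exists(f("rates.tsv")))
    pieces$rates <- long(utils::read.delim(f("rates.tsv")), "growth",
                         "sample_id")
  if (file.exists(f("recovery.tsv")))
    pieces$recovery <- long(utils::read.delim(f("recovery.tsv")), "recovery",
                            "subject")
  if (file.exists(f("dnds.tsv")))
    pieces$dnds <- long(utils::read.delim(f("dnds.tsv")), "dnds", "dataset")
  if (file.exists(f("rnapc_frequencies.tsv"))) {
    fr <- utils::read.delim(f("rnapc_frequencies.tsv"))
    fr$item <- paste0("cycle", fr$cycle, ":", fr$category)
    pieces$freq <- long(fr[, c("item", "n", "percent")], "classify", "item")
  }
  if (!length(pieces))
    stop("no stage outputs found under '", runDir, "'")
  summary <- do.call(rbind, pieces)
  rownames(summary) <- NULL
  .writeTsv(summary, file.path(runDir, "summary.tsv"))
  invisible(summary)
}
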