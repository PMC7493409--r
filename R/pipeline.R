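#' Configuration for an end-to-end pipeline run
#'
#' Exactly one of `input` (paths to observed data) or `simulator` (a
#' [ripSimConfig()]) must be supplied.
#'
#' @param outDir Output directory for the report bundle.
#' @param seed Integer seed used for every stochastic stage (bootstrap,
#'   simulation).
#' @param input Optional list with `fasta`, `metadata` (TSV path or NULL)
#'   and optionally `regions` (YAML path).
#' @param simulator Optional [ripSimConfig()].
#' @param map [RegionMap] used when `input$regions` is absent.
#' @param minTransitions,dominanceRatio Pseudogene-calling thresholds.
#' @param scope `"amplified"` or `"full"` comparison scope (see
#'   [ripScan()]).
#' @param bootstrapReps NJ bootstrap replicates for the combined tree
#'   (default 0 = skip).
#' @param logLevel `"info"` or `"quiet"`.
#' @return List of class `RunConfig`.
#' @export
runConfig <- function(outDir, seed, input = NULL, simulator = NULL,
                      map = defaultRegionMap(), minTransitions = 3,
                      dominanceRatio = 2, scope = c("amplified", "full"),
                      bootstrapReps = 0, logLevel = c("info", "quiet")) {
  if (is.null(input) == is.null(simulator))
    stop("exactly one of `input` and `simulator` must be set")
  structure(list(outDir = outDir, seed = as.integer(seed), input = input,
                 simulator = simulator, map = map,
                 minTransitions = minTransitions,
                 dominanceRatio = dominanceRatio,
                 scope = match.arg(scope), bootstrapReps = bootstrapReps,
                 logLevel = match.arg(logLevel)),
            class = "RunConfig")
}

.stage <- function(name, quiet, expr) {
  if (!quiet) message("[", name, "] ...")
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline and write a report bundle
#'
#' Chains, in order: data ingest or simulation; pseudogene scanning and
#' calling; haplotype collapsing (functional and called-pseudogene records
#' separately, the pseudogenes on the amplified interval); composition and
#' p-distance tables; the dataset-level mutation/occurrence summary; and NJ
#' trees for the functional-only, pseudogene-only and combined datasets
#' (the three-dataset convention). All artifacts are written under
#' `config$outDir` together with a Markdown report and a manifest of file
#' checksums; the same config and seed reproduce the bundle byte for byte.
#'
#' @param config A [runConfig()].
#' @return Invisibly, a list with the in-memory results (`records`,
#'   `scan`, `summary`, `haplotypes`, `composition`, `distances`, `trees`,
#'   `paths`).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  quiet <- config$logLevel == "quiet"
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outDir, f)
  map <- config$map
  set.seed(config$seed)

  records <- .stage("ingest", quiet, {
    if (!is.null(config$simulator)) {
      sim <- simulatePopulation(config$simulator)
      writeSimulatedDataset(sim, out("simulated"))
      sim$records
    } else {
      if (!is.null(config$input$regions))
        map <- readRegionMap(config$input$regions)
      if (!is.null(config$input$metadata) &&
          !file.exists(config$input$metadata))
        stop("metadata file not found: ", config$input$metadata)
      readItsFasta(config$input$fasta, config$input$metadata)
    }
  })

  scan <- .stage("ripscan", quiet,
    ripScan(records, map = map, scope = config$scope,
            minTransitions = config$minTransitions,
            dominanceRatio = config$dominanceRatio))
  if (nrow(scan$calls)) .writeTsv(scan$calls, out("pseudogene_calls.tsv"))

  st <- seqStatus(records)
  calledPseudo <- if (nrow(scan$calls))
    scan$calls$query[scan$calls$status == "pseudogene"] else character()
  funIds <- names(st)[st == "functional"]

  haps <- .stage("haplotypes", quiet, {
    htF <- collapseHaplotypes(records[funIds])
    htP <- if (length(calledPseudo) >= 1) {
      ps <- records[calledPseudo]
      amp <- map@amplified
      psAmp <- itsSequenceSet(
        stats::setNames(vapply(as.character(sequences(ps)), .amplifiedView,
                               character(1), map = map),
                        seqIds(ps)),
        cbind(id = seqIds(ps), as.data.frame(seqMeta(ps))))
      collapseHaplotypes(psAmp)
    } else NULL
    writeHaplotypeTable(htF, records, out("haplotypes_functional.tsv"))
    if (!is.null(htP))
      writeHaplotypeTable(htP, records, out("haplotypes_pseudogene.tsv"))
    list(functional = htF, pseudogene = htP)
  })

  comp <- .stage("composition", quiet, {
    cf <- compositionTable(records[funIds])
    cf$group <- "functional"
    cp <- if (length(calledPseudo)) {
      z <- compositionTable(records[calledPseudo],
                            region = NULL)
      z$length <- nchar(vapply(as.character(sequences(records[calledPseudo])),
                               .amplifiedView, character(1), map = map))
      z$gc <- gcContent(vapply(as.character(sequences(records[calledPseudo])),
                               .amplifiedView, character(1), map = map))
      z$group <- "pseudogene"
      z
    } else NULL
    res <- rbind(cf, cp)
    .writeTsv(res, out("composition.tsv"))
    res
  })

  dists <- .stage("pdist", quiet, {
    ampView <- function(ids) stats::setNames(
      vapply(as.character(sequences(records[ids])), .amplifiedView,
             character(1), map = map), ids)
    dF <- if (length(funIds) >= 2) pDistanceMatrix(ampView(funIds)) else NULL
    dP <- if (length(calledPseudo) >= 2)
      pDistanceMatrix(ampView(calledPseudo)) else NULL
    dC <- if (length(funIds) + length(calledPseudo) >= 3)
      pDistanceMatrix(ampView(c(funIds, calledPseudo))) else NULL
    if (!is.null(dF)) writeDistanceMatrix(dF, out("pdist_functional.tsv"))
    if (!is.null(dP)) writeDistanceMatrix(dP, out("pdist_pseudogene.tsv"))
    if (!is.null(dC)) writeDistanceMatrix(dC, out("pdist_combined.tsv"))
    list(functional = dF, pseudogene = dP, combined = dC)
  })

  summ <- .stage("summary", quiet, {
    gs <- groupMutationSummary(scan, records)
    .writeTsv(gs$mutation, out("mutation_summary.tsv"))
    .writeTsv(gs$byRegion, out("mutation_by_region.tsv"))
    .writeTsv(gs$occurrence, out("occurrence.tsv"))
    gs
  })

  trees <- .stage("njtree", quiet, {
    mk <- function(pm, file) {
      if (is.null(pm) || length(pm$ids) < 3 || any(is.na(pm$d))) return(NULL)
      tr <- njTree(pm)
      writeNewick(tr, out(file))
      tr
    }
    list(functional = mk(dists$functional, "tree_functional.nwk"),
         pseudogene = mk(dists$pseudogene, "tree_pseudogene.nwk"),
         combined = mk(dists$combined, "tree_combined.nwk"))
  })

  .stage("report", quiet, {
    occ <- summ$occurrence[summ$occurrence$locality == "(all)", ]
    lines <- c(
      "# ITS pseudogene pipeline report", "",
      paste0("- seed: ", config$seed),
      paste0("- thresholds: min_transitions=", config$minTransitions,
             ", dominance_ratio=", config$dominanceRatio,
             ", scope=", config$scope),
      paste0("- records: ", length(records), " (",
             length(funIds), " functional, ", length(calledPseudo),
             " called pseudogene)"),
      paste0("- occurrence: ", occ$n_carriers, "/", occ$n_tested,
             " individuals = ", sprintf("%.2f%%", 100 * occ$rate),
             " (raw ", sprintf("%.6f", occ$rate), ")"),
      paste0("- functional haplotypes: ", nHaplotypes(haps$functional)),
      paste0("- pseudogene haplotypes: ",
             if (is.null(haps$pseudogene)) 0 else
               nHaplotypes(haps$pseudogene)),
      if (!is.na(summ$mutation$f_CtoT))
        paste0("- mean mutation frequencies (pseudogenes): C->T ",
               sprintf("%.2f%%", 100 * summ$mutation$f_CtoT), ", G->A ",
               sprintf("%.2f%%", 100 * summ$mutation$f_GtoA), ", other ",
               sprintf("%.2f%%", 100 * summ$mutation$f_other)),
      "")
    writeLines(lines, out("report.md"))
  })

  files <- sort(setdiff(list.files(config$outDir, recursive = TRUE),
                        "manifest.tsv"))
  manifest <- data.frame(
    file = files,
    md5 = vapply(file.path(config$outDir, files), function(f)
      as.character(tools::md5sum(f)), character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  .writeTsv(manifest, out("manifest.tsv"))

  invisible(list(records = records, scan = scan, summary = summ,
                 haplotypes = haps, composition = comp, distances = dists,
                 trees = trees,
                 paths = file.path(config$outDir, c(files, "manifest.tsv"))))
}
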