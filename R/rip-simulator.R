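#' Default RIP context weights
#'
#' Relative mutability of the four RIP dinucleotide classes, heavily
#' favouring CpA<->TpA / TpG<->TpA so that the canonical RIP context
#' preference emerges in downstream RIPCAL-style comparisons.
#'
#' @return Named numeric weights summing to 1.
#' @export
defaultContextWeights <- function() {
  c("CpA<->TpA" = 0.55, "CpC<->TpC" = 0.20, "CpG<->TpG" = 0.15,
    "CpT<->TpT" = 0.10)
}

.contextOfSites <- function(chv) {
  # context class of every C (3' neighbour) and G (5' neighbour) site,
  # evaluated on the pre-mutation sequence
  L <- length(chv)
  pos <- which(chv == "C" | chv == "G")
  cls <- rep("nonRIP", length(pos))
  isC <- chv[pos] == "C"
  nb <- rep(NA_character_, length(pos))
  nb[isC] <- ifelse(pos[isC] < L, chv[pmin(pos[isC] + 1L, L)], NA)
  nb[!isC] <- ifelse(pos[!isC] > 1L, chv[pmax(pos[!isC] - 1L, 1L)], NA)
  hit <- isC & nb %in% names(.CTX_FOR_CT)
  cls[hit] <- .CTX_FOR_CT[nb[hit]]
  hit <- !isC & nb %in% names(.CTX_FOR_GA)
  cls[hit] <- .CTX_FOR_GA[nb[hit]]
  list(pos = pos, isC = isC, class = cls)
}

#' Apply one RIP event to a sequence
#'
#' Mutates each G:C site independently: every C (and every G, which is a C
#' on the antisense strand) converts to T (resp. A) with probability
#' `severity` scaled by the relative weight of its dinucleotide context
#' class. Weights are rescaled to mean 1 across the four classes, so with
#' uniform weights every eligible site mutates with probability exactly
#' `severity` (and `severity = 1` saturates every G:C pair); site
#' probabilities are capped at 1. Contexts are evaluated on the
#' pre-mutation sequence (single-pass RIP), avoiding any dependence on
#' mutation order; edge sites without a flanking neighbour are recorded as
#' `nonRIP` and mutate with the unscaled `severity`.
#'
#' Uses the R random number generator: seed via [set.seed()] (or the
#' simulator configs) for reproducibility.
#'
#' @param seq Character or `DNAString` over A/C/G/T.
#' @param severity Per-event mutation probability of an (average-context)
#'   G:C site, in `[0, 1]`. The classic upper bound for a single passage
#'   through the sexual cycle is ~0.3.
#' @param contextWeights Named weights over the four RIP classes (any
#'   positive scale; default [defaultContextWeights()]).
#' @param multiPass Number of passes; passes beyond the first re-evaluate
#'   contexts on the already-mutated sequence in position order (default 1).
#' @return List with `seq` (mutated character string) and `events`
#'   (data.frame: `position`, `ref`, `query`, `context_class`).
#' @export
ripMutate <- function(seq, severity, contextWeights = defaultContextWeights(),
                      multiPass = 1L) {
  stopifnot(severity >= 0, severity <= 1)
  chv <- .chars(seq)
  if (any(!.isACGT(chv))) stop("ripMutate requires an ungapped A/C/G/T sequence")
  ripClasses <- setdiff(contextClasses(), "nonRIP")
  w <- if (is.null(names(contextWeights)) && length(contextWeights) == 4)
    stats::setNames(contextWeights, ripClasses) else
    contextWeights[ripClasses]
  if (any(is.na(w)) || any(w < 0) || sum(w) == 0)
    stop("invalid context weights: supply positive weights for ",
         paste(ripClasses, collapse = ", "))
  mult <- c(w * 4 / sum(w), nonRIP = 1)
  allev <- list()
  for (pass in seq_len(multiPass)) {
    ctx <- .contextOfSites(chv)
    p <- pmin(1, severity * mult[ctx$class])
    hit <- stats::runif(length(ctx$pos)) < p
    if (any(hit)) {
      pos <- ctx$pos[hit]
      refb <- chv[pos]
      newb <- ifelse(refb == "C", "T", "A")
      chv[pos] <- newb
      allev[[pass]] <- data.frame(position = pos, ref = refb, query = newb,
                                  context_class = unname(ctx$class[hit]),
                                  stringsAsFactors = FALSE)
    }
  }
  events <- if (length(allev)) do.call(rbind, allev) else
    data.frame(position = integer(), ref = character(), query = character(),
               context_class = character(), stringsAsFactors = FALSE)
  events <- events[order(events$position), , drop = FALSE]
  row.names(events) <- NULL
  list(seq = paste(chv, collapse = ""), events = events)
}

#' Generate a random ancestral ITS sequence
#'
#' Draws bases i.i.d. at the target GC fraction and plants the 8-nt
#' GC-rich motif `CGCCCCGG` inside ITS1 (positions 60-67 of the default
#' 562-nt layout), the motif whose deletion produces the 554-nt length
#' variant.
#'
#' @param length Sequence length in nt (default 562).
#' @param gc Target GC fraction (default 0.6313, the functional ITS mean).
#' @param motif,motifStart Planted motif and its start (set `motif = NULL`
#'   to skip planting).
#' @return Character sequence.
#' @export
randomAncestor <- function(length = 562L, gc = 0.6313,
                           motif = "CGCCCCGG", motifStart = 60L) {
  # exact base composition (counts, not i.i.d. draws) so the realized GC
  # fraction matches the target to rounding, whatever the seed
  nGC <- round(length * gc)
  nG <- nGC %/% 2L; nC <- nGC - nG
  nAT <- length - nGC
  nA <- nAT %/% 2L; nT <- nAT - nA
  b <- sample(rep(c("A", "C", "G", "T"), c(nA, nC, nG, nT)))
  if (!is.null(motif)) {
    m <- .chars(motif)
    b[motifStart:(motifStart + length(m) - 1L)] <- m
  }
  paste(b, collapse = "")
}

#' Simulate a radiation of functional ITS haplotypes
#'
#' Each haplotype descends independently from the ancestor with per-site
#' substitution probability `divergence / 2` (uniform over sites and over
#' the three alternative bases), so the expected pairwise p-distance
#' between haplotypes is approximately `divergence`. No indels are
#' introduced unless `deletionVariants` marks haplotypes that should carry
#' the planted 8-nt motif deletion (yielding the shorter length variant).
#'
#' @param ancestor Character sequence.
#' @param nHaplotypes Number of haplotypes.
#' @param divergence Target expected pairwise p-distance, in `[0, 0.05]`.
#' @param deletionVariants Integer indices of haplotypes carrying the motif
#'   deletion (default none).
#' @param motif,motifStart The planted motif to delete.
#' @return Named character vector `f1`, `f2`, ... of haplotype sequences.
#' @export
simulateFunctionalRadiation <- function(ancestor, nHaplotypes, divergence,
                                        deletionVariants = integer(),
                                        motif = "CGCCCCGG",
                                        motifStart = 60L) {
  stopifnot(divergence >= 0, divergence <= 0.05)
  rate <- divergence / 2
  base <- .chars(ancestor)
  out <- character(nHaplotypes)
  for (i in seq_len(nHaplotypes)) {
    chv <- base
    hit <- which(stats::runif(length(chv)) < rate)
    for (p in hit)
      chv[p] <- sample(setdiff(c("A", "C", "G", "T"), chv[p]), 1)
    s <- paste(chv, collapse = "")
    if (i %in% deletionVariants) {
      # delete the planted motif window (even if a substitution landed in it)
      s <- paste0(substr(s, 1, motifStart - 1L),
                  substr(s, motifStart + nchar(motif), nchar(s)))
    }
    out[i] <- s
  }
  stats::setNames(out, paste0("f", seq_len(nHaplotypes)))
}

#' Configuration for the population RIP simulator
#'
#' Builds a validated configuration whose defaults are the study
#' conditions emulated throughout the package: 147 individuals spread over
#' five provinces, 43 of them carrying pseudogenes (none in Yunnan),
#' 17 functional haplotypes at pairwise divergence 0.006 with a
#' geometrically dominant haplotype, RIP severity 0.20 biased toward the
#' CpA<->TpA context, 1-8 pseudogene haplotypes per carrier (truncated
#' geometric), and a shared ancestral RIP origin with low-rate neutral
#' divergence among copies.
#'
#' @param seed Mandatory integer seed.
#' @param nIndividuals Total individuals (default 147).
#' @param localities data.frame with columns `locality`, `n` (individuals)
#'   and `occurrence` (per-locality probability that an individual carries
#'   pseudogenes). Default: the five-province layout with overall
#'   occurrence 43/147 and zero in Yunnan.
#' @param nFunctionalHaplotypes,functionalDivergence Functional radiation
#'   size and target pairwise p-distance (defaults 17 and 0.006).
#' @param dominantShare Population frequency of the dominant functional
#'   haplotype (default 0.62); the remaining haplotypes are equifrequent.
#' @param severity RIP severity in `[0, 1]` (default 0.20).
#' @param contextWeights Context weights (default
#'   [defaultContextWeights()]).
#' @param copyGeomP Truncated-geometric parameter of the pseudogene
#'   haplotype count per carrier on 1..8 (default 0.35, mean ~2.9 copies).
#' @param sharedOrigin Logical: one ancestral RIP event propagated through
#'   the whole population with subsequent neutral divergence among copies
#'   (`TRUE`, default) versus independent RIP of each copy from its own
#'   functional sequence (`FALSE`).
#' @param pseudoDivergence Per-lineage neutral substitution rate applied to
#'   shared-origin copies (default 0.022, giving pairwise pseudogene
#'   p-distance near 0.044).
#' @param carrierMode `"deterministic"` (exact largest-remainder carrier
#'   counts per locality; default) or `"bernoulli"`.
#' @param ancestorLength,ancestorGC Ancestor generator parameters (562 nt,
#'   GC 0.6313) used when `ancestor` is `NULL`.
#' @param ancestor Optional explicit ancestor sequence.
#' @param trimPseudogenesToAmplified Emit pseudogene records restricted to
#'   the map's amplified interval (default `FALSE`).
#' @param map [RegionMap] used for the amplified interval.
#' @return List of class `RipSimConfig`.
#' @export
ripSimConfig <- function(seed,
                         nIndividuals = 147L,
                         localities = NULL,
                         nFunctionalHaplotypes = 17L,
                         functionalDivergence = 0.006,
                         dominantShare = 0.62,
                         severity = 0.20,
                         contextWeights = defaultContextWeights(),
                         copyGeomP = 0.35,
                         sharedOrigin = TRUE,
                         pseudoDivergence = 0.022,
                         carrierMode = c("deterministic", "bernoulli"),
                         ancestorLength = 562L,
                         ancestorGC = 0.6313,
                         ancestor = NULL,
                         trimPseudogenesToAmplified = FALSE,
                         map = defaultRegionMap()) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  carrierMode <- match.arg(carrierMode)
  if (is.null(localities)) {
    localities <- data.frame(
      locality = c("Qinghai", "Tibet", "Sichuan", "Yunnan", "Gansu"),
      n = c(88L, 23L, 18L, 14L, 4L),
      occurrence = c(rep(43 / 133, 3), 0, 43 / 133),
      stringsAsFactors = FALSE)
    if (nIndividuals != 147L) {
      localities$n <- .apportion(nIndividuals, localities$n)
    }
  }
  stopifnot(sum(localities$n) == nIndividuals,
            all(localities$occurrence >= 0 & localities$occurrence <= 1),
            severity >= 0, severity <= 1,
            copyGeomP > 0, copyGeomP <= 1)
  structure(list(seed = as.integer(seed), nIndividuals = as.integer(nIndividuals),
                 localities = localities,
                 nFunctionalHaplotypes = as.integer(nFunctionalHaplotypes),
                 functionalDivergence = functionalDivergence,
                 dominantShare = dominantShare, severity = severity,
                 contextWeights = contextWeights, copyGeomP = copyGeomP,
                 sharedOrigin = sharedOrigin,
                 pseudoDivergence = pseudoDivergence,
                 carrierMode = carrierMode,
                 ancestorLength = as.integer(ancestorLength),
                 ancestorGC = ancestorGC, ancestor = ancestor,
                 trimPseudogenesToAmplified = trimPseudogenesToAmplified,
                 map = map),
            class = "RipSimConfig")
}

.rtruncgeom <- function(n, p, kmax = 8L) {
  # truncated geometric on 1..kmax
  probs <- p * (1 - p)^(0:(kmax - 1L))
  sample.int(kmax, n, replace = TRUE, prob = probs / sum(probs))
}

.neutralMutate <- function(chv, rate) {
  hit <- which(stats::runif(length(chv)) < rate)
  for (p in hit)
    chv[p] <- sample(setdiff(c("A", "C", "G", "T"), chv[p]), 1)
  chv
}

#' Simulate a population of individuals with RIP-mutated ITS paralogs
#'
#' Draws the functional haplotype radiation, assigns individuals to
#' localities, selects pseudogene carriers (deterministically or by
#' Bernoulli sampling of the per-locality occurrence), and generates each
#' carrier's 1-8 pseudogene copies by RIP mutation — either independently
#' from the carrier's own functional copy, or (shared origin) from a
#' single ancestral RIP product followed by low-rate neutral divergence. Ground truth (status, RIP event counts and positions) is
#' kept in a separate truth table and in the metadata `truth_status`
#' column; the released `status` of pseudogene records is `candidate`, so
#' detection must be earned.
#'
#' Identical config (including seed) gives byte-identical output.
#'
#' @param config A [ripSimConfig()].
#' @return List of class `RipSimResult` with `records` ([ItsSequenceSet]),
#'   `truth` (data.frame: `id`, `truth_status`, `n_events`,
#'   `event_positions` semicolon-joined, in full-sequence coordinates),
#'   `functionalHaplotypes` (named character) and `config`.
#' @export
simulatePopulation <- function(config) {
  stopifnot(inherits(config, "RipSimConfig"))
  set.seed(config$seed)
  ancestor <- if (is.null(config$ancestor))
    randomAncestor(config$ancestorLength, config$ancestorGC) else
    config$ancestor
  fh <- simulateFunctionalRadiation(ancestor, config$nFunctionalHaplotypes,
                                    config$functionalDivergence)
  loc <- config$localities
  indLoc <- rep(loc$locality, loc$n)
  nInd <- length(indLoc)
  indIds <- sprintf("CS%03d", seq_len(nInd))
  # haplotype frequencies: one dominant haplotype, the rest equifrequent,
  # so both the dominant share and the number of observed haplotypes in a
  # study-sized sample match field surveys
  k <- config$nFunctionalHaplotypes
  hw <- if (k == 1) 1 else
    c(config$dominantShare, rep((1 - config$dominantShare) / (k - 1), k - 1))
  hIdx <- sample.int(k, nInd, replace = TRUE, prob = hw)
  # carrier selection
  carrier <- logical(nInd)
  if (config$carrierMode == "deterministic") {
    target <- round(sum(loc$n * loc$occurrence))
    perLoc <- .apportion(target, loc$n * loc$occurrence)
    for (k in seq_len(nrow(loc))) {
      inL <- which(indLoc == loc$locality[k])
      if (perLoc[k] > 0) carrier[inL[seq_len(perLoc[k])]] <- TRUE
    }
  } else {
    occ <- loc$occurrence[match(indLoc, loc$locality)]
    carrier <- stats::runif(nInd) < occ
  }
  kCopies <- integer(nInd)
  kCopies[carrier] <- .rtruncgeom(sum(carrier), config$copyGeomP)
  # shared origin: one ancestral RIP product propagated through the
  # population, with subsequent neutral divergence among copies
  sharedRip <- if (config$sharedOrigin)
    ripMutate(ancestor, config$severity, config$contextWeights) else NULL
  ids <- character(); seqs <- character()
  meta <- list(); truth <- list()
  addRec <- function(id, s, ind, l, status, truthStatus, events) {
    ids <<- c(ids, id); seqs <<- c(seqs, s)
    meta[[id]] <<- data.frame(individual_id = ind, locality = l,
                              source = "simulated", status = status,
                              truth_status = truthStatus,
                              stringsAsFactors = FALSE)
    truth[[id]] <<- data.frame(
      id = id, truth_status = truthStatus,
      n_events = if (is.null(events)) 0L else nrow(events),
      event_positions = if (is.null(events)) "" else
        paste(events$position, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  amp <- config$map@amplified
  for (i in seq_len(nInd)) {
    fseq <- fh[[hIdx[i]]]
    addRec(paste0(indIds[i], "_ITS"), fseq, indIds[i], indLoc[i],
           "functional", "functional", NULL)
    if (carrier[i]) {
      for (k in seq_len(kCopies[i])) {
        if (config$sharedOrigin) {
          chv <- .neutralMutate(.chars(sharedRip$seq),
                                config$pseudoDivergence)
          s <- paste(chv, collapse = "")
          events <- sharedRip$events
        } else {
          m <- ripMutate(fseq, config$severity, config$contextWeights)
          s <- m$seq
          events <- m$events
        }
        if (config$trimPseudogenesToAmplified) {
          s <- substr(s, amp[1], amp[2])
          events <- events[events$position >= amp[1] &
                             events$position <= amp[2], , drop = FALSE]
        }
        addRec(paste0(indIds[i], "_P", k), s, indIds[i], indLoc[i],
               "candidate", "pseudogene", events)
      }
    }
  }
  records <- itsSequenceSet(stats::setNames(seqs, ids),
                            do.call(rbind, meta))
  structure(list(records = records,
                 truth = do.call(rbind, c(truth, make.row.names = FALSE)),
                 functionalHaplotypes = fh, ancestor = ancestor,
                 config = config),
            class = "RipSimResult")
}

#' @export
print.RipSimResult <- function(x, ...) {
  st <- x$truth$truth_status
  cat("RipSimResult:", sum(st == "functional"), "functional +",
      sum(st == "pseudogene"), "pseudogene records over",
      x$config$nIndividuals, "individuals (seed", x$config$seed, ")\n")
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits the FASTA of all copies, the metadata TSV in the layout
#' [readItsFasta()] expects, the ground-truth TSV, and a YAML echo of the
#' configuration.
#'
#' @param sim A `RipSimResult`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
writeSimulatedDataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fasta = file.path(dir, "sequences.fasta"),
             metadata = file.path(dir, "metadata.tsv"),
             truth = file.path(dir, "truth.tsv"),
             config = file.path(dir, "config.yaml"))
  writeItsFasta(sim$records, paths["fasta"], paths["metadata"])
  .writeTsv(sim$truth, paths["truth"])
  cfg <- sim$config
  cfg$map <- list(its1 = as.integer(cfg$map@its1),
                  r5_8s = as.integer(cfg$map@r5_8s),
                  its2 = as.integer(cfg$map@its2),
                  amplified = as.integer(cfg$map@amplified))
  cfg$localities <- as.list(cfg$localities)
  yaml::write_yaml(unclass(cfg), paths["config"])
  invisible(paths)
}
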