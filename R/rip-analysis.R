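#' Global alignment of a candidate copy against its functional counterpart
#'
#' Deterministic Needleman-Wunsch alignment (match +1, mismatch -1, gap
#' opening 5, gap extension 2) of a query ITS copy against its reference.
#' Gap columns are flagged downstream and excluded from substitution
#' calling.
#'
#' @param query,reference Sequences (character or `DNAString`); gaps are
#'   stripped before alignment. Names, if present, are carried along as ids.
#' @return Object of class `pairAlignment`: list with gapped strings `q` and
#'   `r`, ids `query_id`/`reference_id`, and the alignment `score`.
#' @export
pairAlign <- function(query, reference) {
  qid <- if (!is.null(names(query))) names(query)[1] else "query"
  rid <- if (!is.null(names(reference))) names(reference)[1] else "reference"
  aln <- .globalAlign(as.character(query)[1], as.character(reference)[1])
  structure(list(q = aln$q, r = aln$r, query_id = qid, reference_id = rid,
                 score = aln$score),
            class = "pairAlignment")
}

#' @export
print.pairAlignment <- function(x, ...) {
  cat("pairAlignment", x$query_id, "vs", x$reference_id, "(",
      nchar(x$q), "columns, score", x$score, ")\n")
  invisible(x)
}

.CTX_FOR_CT <- c(A = "CpA<->TpA", C = "CpC<->TpC", G = "CpG<->TpG",
                 T = "CpT<->TpT")
.CTX_FOR_GA <- c(T = "CpA<->TpA", G = "CpC<->TpC", C = "CpG<->TpG",
                 A = "CpT<->TpT")

#' Classify substitutions of an aligned pair into RIP mutation events
#'
#' One event is emitted per mismatch column in which both rows carry an
#' unambiguous base. Events are typed `C->T`, `G->A` (the two faces of a
#' G:C -> A:T transition) or `other`. For C->T the dinucleotide context is
#' the reference base and its 3' neighbour; for G->A it is the reference
#' base and its 5' neighbour, i.e. the CpN context read on the
#' complementary strand (TpG on the reference strand is CpA on the
#' complement). Contexts are read from the ungapped reference sequence, so
#' a neighbouring alignment gap does not alter them; events at sequence
#' edges (no neighbour) or with an ambiguous neighbour are classed
#' `nonRIP`, as are all `other` substitutions.
#'
#' @param aln A `pairAlignment` from [pairAlign()], or equivalent list with
#'   gapped strings `q` and `r`.
#' @param map Optional [RegionMap] used to label each event's region.
#' @param refOffset Coordinate of the first reference base within the map's
#'   frame (use the amplified-interval start when the reference is the
#'   amplified subsequence). Default 1.
#' @return data.frame with columns `position` (reference coordinate,
#'   1-based ungapped, in the map's frame), `ref`, `query`, `type`,
#'   `context_class`, `region`.
#' @export
classifySubstitutions <- function(aln, map = NULL, refOffset = 1L) {
  q <- .chars(aln$q); r <- .chars(aln$r)
  refseq <- r[r != "-"]
  refpos <- cumsum(r != "-")
  ev <- which(r != "-" & q != "-" & .isACGT(r) & .isACGT(q) & q != r)
  n <- length(ev)
  pos <- refpos[ev]
  ref <- r[ev]; qry <- q[ev]
  type <- rep("other", n)
  type[ref == "C" & qry == "T"] <- "C->T"
  type[ref == "G" & qry == "A"] <- "G->A"
  ctx <- rep("nonRIP", n)
  if (n) {
    ct <- type == "C->T"
    nb <- ifelse(pos[ct] < length(refseq), refseq[pmin(pos[ct] + 1L,
                                                       length(refseq))], "")
    ctx[ct] <- ifelse(nb %in% names(.CTX_FOR_CT), .CTX_FOR_CT[nb], "nonRIP")
    ga <- type == "G->A"
    nb <- ifelse(pos[ga] > 1L, refseq[pmax(pos[ga] - 1L, 1L)], "")
    ctx[ga] <- ifelse(nb %in% names(.CTX_FOR_GA), .CTX_FOR_GA[nb], "nonRIP")
  }
  outpos <- pos + as.integer(refOffset) - 1L
  data.frame(position = outpos, ref = ref, query = qry, type = type,
             context_class = ctx,
             region = if (is.null(map)) rep(NA_character_, n) else
               regionOfPosition(map, outpos),
             stringsAsFactors = FALSE)
}

#' Comparable-site counts of an aligned pair, by region
#'
#' A site is comparable iff both rows carry an unambiguous base (pairwise
#' deletion). Also counts comparable sites whose reference base is C or G,
#' the denominators for the per-C-site / per-G-site mutation frequencies.
#'
#' @inheritParams classifySubstitutions
#' @return data.frame with `region`, `comparable`, `c_sites`, `g_sites`
#'   (one row per region present plus a `total` row).
#' @export
alignmentSiteCounts <- function(aln, map = NULL, refOffset = 1L) {
  q <- .chars(aln$q); r <- .chars(aln$r)
  refpos <- cumsum(r != "-")
  comp <- r != "-" & q != "-" & .isACGT(r) & .isACGT(q)
  pos <- refpos[comp] + as.integer(refOffset) - 1L
  reg <- if (is.null(map)) rep("all", sum(comp)) else regionOfPosition(map, pos)
  refc <- r[comp]
  lev <- unique(c(if (is.null(map)) "all" else
    intersect(c("ITS1", "5.8S", "ITS2", "flank"), reg), reg))
  tab <- function(mask) as.integer(table(factor(reg[mask], levels = lev)))
  out <- data.frame(region = lev,
                    comparable = tab(rep(TRUE, length(reg))),
                    c_sites = tab(refc == "C"),
                    g_sites = tab(refc == "G"),
                    stringsAsFactors = FALSE)
  rbind(out, data.frame(region = "total", comparable = sum(comp),
                        c_sites = sum(refc == "C"),
                        g_sites = sum(refc == "G"),
                        stringsAsFactors = FALSE))
}

#' Per-region mutation spectrum of one query-vs-reference comparison
#'
#' Tallies C->T, G->A and other substitutions per region and overall, with
#' frequencies on two denominators: `f_*` per comparable site, and
#' `f_CtoT_perC` / `f_GtoA_perG` per comparable reference C (resp. G) site.
#' The dominant RIP dinucleotide class is the argmax of the context-class
#' tallies (`mixed` on ties, `none` when there are no RIP-type events).
#'
#' @param events Event table from [classifySubstitutions()].
#' @param sites Site-count table from [alignmentSiteCounts()] for the same
#'   comparison.
#' @return Object of class `mutationSpectrum`: a data.frame (one row per
#'   region plus `total`) with counts and frequencies, plus attributes
#'   `context` (named tally over the five context classes) and
#'   `dominant_class`.
#' @export
mutationSpectrum <- function(events, sites) {
  reg <- sites$region
  evreg <- events$region
  if (all(is.na(evreg))) evreg <- rep("all", nrow(events))
  cnt <- function(region, what) {
    inreg <- if (region == "total") rep(TRUE, nrow(events)) else evreg == region
    sum(inreg & what)
  }
  out <- sites
  out$n_CtoT <- vapply(reg, cnt, integer(1) + 0, what = events$type == "C->T")
  out$n_GtoA <- vapply(reg, cnt, integer(1) + 0, what = events$type == "G->A")
  out$n_other <- vapply(reg, cnt, integer(1) + 0, what = events$type == "other")
  frac <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  out$f_CtoT <- frac(out$n_CtoT, out$comparable)
  out$f_GtoA <- frac(out$n_GtoA, out$comparable)
  out$f_other <- frac(out$n_other, out$comparable)
  out$f_CtoT_perC <- frac(out$n_CtoT, out$c_sites)
  out$f_GtoA_perG <- frac(out$n_GtoA, out$g_sites)
  ctxLev <- contextClasses()
  ctx <- table(factor(events$context_class, levels = ctxLev))
  ripctx <- ctx[setdiff(ctxLev, "nonRIP")]
  dominant <- if (sum(ripctx) == 0) "none" else {
    top <- which(ripctx == max(ripctx))
    if (length(top) > 1) "mixed" else names(ripctx)[top]
  }
  structure(out, context = stats::setNames(as.integer(ctx), ctxLev),
            dominant_class = dominant, class = c("mutationSpectrum",
                                                 "data.frame"))
}

#' Call pseudogene status from a mutation spectrum
#'
#' A query is called `pseudogene` when its G:C -> A:T transition load
#' against its own functional counterpart is both absolutely and relatively
#' convincing: `n_CtoT + n_GtoA >= minTransitions` and
#' `n_CtoT + n_GtoA >= dominanceRatio * n_other`. The defaults (3 and 2)
#' guard against sequencing error while comfortably recovering RIP-scale
#' pseudogenes, which carry dozens of transitions per amplicon.
#'
#' @param spectrum A `mutationSpectrum`.
#' @param minTransitions Minimum number of transitions (default 3).
#' @param dominanceRatio Required ratio of transitions to other
#'   substitutions (default 2).
#' @return data.frame (one row) with `status` (`pseudogene` /
#'   `functional-like`), the evidence counts and the thresholds used.
#' @export
callPseudogene <- function(spectrum, minTransitions = 3, dominanceRatio = 2) {
  tot <- spectrum[spectrum$region == "total", ]
  ntr <- tot$n_CtoT + tot$n_GtoA
  status <- if (ntr >= minTransitions && ntr >= dominanceRatio * tot$n_other)
    "pseudogene" else "functional-like"
  data.frame(status = status, n_transitions = ntr, n_other = tot$n_other,
             comparable = tot$comparable,
             min_transitions = minTransitions,
             dominance_ratio = dominanceRatio,
             dominant_class = attr(spectrum, "dominant_class"),
             stringsAsFactors = FALSE)
}

#' Compare one query against one reference end to end
#'
#' Convenience chain: [pairAlign()] -> [classifySubstitutions()] ->
#' [alignmentSiteCounts()] -> [mutationSpectrum()] -> [callPseudogene()].
#'
#' @inheritParams pairAlign
#' @inheritParams classifySubstitutions
#' @inheritParams callPseudogene
#' @return List with `alignment`, `events`, `spectrum`, `call`.
#' @export
compareToReference <- function(query, reference, map = NULL, refOffset = 1L,
                               minTransitions = 3, dominanceRatio = 2) {
  aln <- pairAlign(query, reference)
  events <- classifySubstitutions(aln, map, refOffset)
  sites <- alignmentSiteCounts(aln, map, refOffset)
  spec <- mutationSpectrum(events, sites)
  list(alignment = aln, events = events, spectrum = spec,
       call = callPseudogene(spec, minTransitions, dominanceRatio))
}

#' RIPCAL-style comparison of a multiple alignment against its consensus
#'
#' The consensus is the alignment member with the highest GC content (the
#' presumed unmutated model; ties resolved to the lexicographically smallest
#' id). Every other sequence is compared column-wise against it and its
#' substitutions are tallied by RIP dinucleotide context class; the
#' alignment-wide ranking orders the four RIP classes by total count.
#'
#' @param x An aligned [ItsSequenceSet]/[ItsAlignment], `DNAStringSet`, or
#'   named character vector (>= 2 sequences, equal lengths).
#' @param consensus `"auto"` (highest GC) or an explicit record id.
#' @return List with `consensus` (id), `tallies` (matrix: sequences x five
#'   context classes), `events` (per-sequence event tables) and `ranking`
#'   (data.frame of the four RIP classes sorted by total count).
#' @export
ripcalCompare <- function(x, consensus = "auto") {
  s <- .asSeqChar(x)
  if (length(s) < 2) stop("ripcalCompare needs an alignment of >= 2 sequences")
  if (length(unique(nchar(s))) != 1) stop("sequences must be aligned")
  ids <- names(s)
  if (identical(consensus, "auto")) {
    gc <- gcContent(s)
    best <- which(gc == max(gc, na.rm = TRUE))
    consensus <- ids[best][order(ids[best])][1]
  } else if (!consensus %in% ids) {
    stop("consensus id '", consensus, "' not in the alignment")
  }
  ref <- s[[consensus]]
  others <- setdiff(ids, consensus)
  ctxLev <- contextClasses()
  tallies <- matrix(0L, length(others), length(ctxLev),
                    dimnames = list(others, ctxLev))
  events <- list()
  for (id in others) {
    ev <- classifySubstitutions(list(q = s[[id]], r = ref))
    events[[id]] <- ev
    tallies[id, ] <- as.integer(table(factor(ev$context_class,
                                             levels = ctxLev)))
  }
  rip <- setdiff(ctxLev, "nonRIP")
  totals <- colSums(tallies)[rip]
  ranking <- data.frame(context_class = names(sort(totals,
                                                   decreasing = TRUE)),
                        n = as.integer(sort(totals, decreasing = TRUE)),
                        stringsAsFactors = FALSE)
  list(consensus = consensus, tallies = tallies, events = events,
       ranking = ranking)
}

#' Composite RIP indices of a sequence
#'
#' The two dinucleotide indices conventionally reported alongside RIP
#' scans: the product index TpA/ApT and the substrate index
#' (CpA + TpG)/(ApC + GpT). RIP-eroded sequences show an elevated product
#' index and a depressed substrate index. Provided as auxiliary outputs;
#' pseudogene calling does not use them.
#'
#' @param x An [ItsSequenceSet], `DNAStringSet`, or character vector.
#' @return data.frame with `id`, `tpa_apt`, `cpa_tpg_over_apc_gpt`
#'   (`NA` where a denominator is zero).
#' @export
ripIndices <- function(x) {
  s <- .asSeqChar(x)
  ids <- if (is.null(names(s))) paste0("s", seq_along(s)) else names(s)
  dn <- Biostrings::dinucleotideFrequency(DNAStringSet(.degap(s)))
  safe <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  data.frame(id = ids,
             tpa_apt = safe(dn[, "TA"], dn[, "AT"]),
             cpa_tpg_over_apc_gpt = safe(dn[, "CA"] + dn[, "TG"],
                                         dn[, "AC"] + dn[, "GT"]),
             row.names = NULL, stringsAsFactors = FALSE)
}

.amplifiedView <- function(seq, map) {
  seq <- .degap(as.character(seq))
  amp <- map@amplified
  if (nchar(seq) >= amp[2]) substr(seq, amp[1], amp[2]) else seq
}

#' Scan a dataset for ITS pseudogenes
#'
#' Compares every candidate (or pre-labelled pseudogene) record against its
#' functional counterpart and calls pseudogene status from the mutation
#' spectrum. The reference for each query is the functional record
#' amplified from the same individual; when several functional clones
#' exist, the one with the highest GC content is used (consistent with the
#' RIPCAL consensus rule). The reference policy for queries whose
#' individual has no functional record is explicit:
#' `"same-individual"` errors, `"consensus"` always uses the globally
#' highest-GC functional record, and `"auto"` (default) prefers the
#' same-individual partner and falls back to the global consensus.
#'
#' With `scope = "amplified"` (default) both query and reference are
#' restricted to the map's amplified interval before alignment; records
#' shorter than the full reference layout (primer-internal amplicons) are
#' used as-is. With `scope = "full"` the full sequences are compared.
#'
#' @param x An [ItsSequenceSet].
#' @param map A [RegionMap] (default [defaultRegionMap()]).
#' @param scope `"amplified"` or `"full"`.
#' @param referencePolicy `"auto"`, `"same-individual"` or `"consensus"`.
#' @param minTransitions,dominanceRatio Calling thresholds, see
#'   [callPseudogene()].
#' @return Object of class `ripScan`: list with `calls` (one row per query:
#'   ids, per-region and total counts, frequencies, dominant class,
#'   status), `spectra` and `events` (named lists), and the thresholds.
#' @export
ripScan <- function(x, map = defaultRegionMap(),
                    scope = c("amplified", "full"),
                    referencePolicy = c("auto", "same-individual",
                                        "consensus"),
                    minTransitions = 3, dominanceRatio = 2) {
  scope <- match.arg(scope)
  referencePolicy <- match.arg(referencePolicy)
  st <- seqStatus(x)
  ind <- individualIds(x)
  queries <- names(st)[st %in% c("candidate", "pseudogene")]
  functionals <- names(st)[st == "functional"]
  if (!length(functionals))
    stop("no functional records to compare against")
  gc <- gcContent(x)
  globalRef <- functionals[order(-gc[functionals], functionals)][1]
  refFor <- function(qid) {
    own <- functionals[ind[functionals] == ind[qid]]
    if (length(own))
      return(own[order(-gc[own], own)][1])
    switch(referencePolicy,
           "same-individual" = stop("no functional counterpart for '", qid,
                                    "' (individual ", ind[qid], ")"),
           globalRef)
  }
  if (referencePolicy == "consensus") refFor <- function(qid) globalRef
  refOffset <- if (scope == "amplified") map@amplified[1] else 1L
  view <- function(id) {
    s <- as.character(x@seqs[[match(id, names(x@seqs))]])
    if (scope == "amplified") .amplifiedView(s, map) else .degap(s)
  }
  rows <- list(); spectra <- list(); events <- list()
  for (qid in queries) {
    rid <- refFor(qid)
    cmp <- compareToReference(stats::setNames(view(qid), qid),
                              stats::setNames(view(rid), rid),
                              map = map, refOffset = refOffset,
                              minTransitions = minTransitions,
                              dominanceRatio = dominanceRatio)
    spectra[[qid]] <- cmp$spectrum
    events[[qid]] <- cmp$events
    tot <- cmp$spectrum[cmp$spectrum$region == "total", ]
    regrow <- function(region, col) {
      v <- cmp$spectrum[cmp$spectrum$region == region, col]
      if (length(v)) v else 0L
    }
    rows[[qid]] <- data.frame(
      query = qid, reference = rid, individual_id = unname(ind[qid]),
      locality = unname(localities(x)[qid]),
      n_CtoT = tot$n_CtoT, n_GtoA = tot$n_GtoA, n_other = tot$n_other,
      comparable = tot$comparable,
      f_CtoT = tot$f_CtoT, f_GtoA = tot$f_GtoA, f_other = tot$f_other,
      f_CtoT_perC = tot$f_CtoT_perC, f_GtoA_perG = tot$f_GtoA_perG,
      n_CtoT_ITS1 = regrow("ITS1", "n_CtoT"),
      n_GtoA_ITS1 = regrow("ITS1", "n_GtoA"),
      n_CtoT_58S = regrow("5.8S", "n_CtoT"),
      n_GtoA_58S = regrow("5.8S", "n_GtoA"),
      n_CtoT_ITS2 = regrow("ITS2", "n_CtoT"),
      n_GtoA_ITS2 = regrow("ITS2", "n_GtoA"),
      dominant_class = cmp$call$dominant_class,
      status = cmp$call$status,
      stringsAsFactors = FALSE)
  }
  calls <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
    else data.frame()
  structure(list(calls = calls, spectra = spectra, events = events,
                 minTransitions = minTransitions,
                 dominanceRatio = dominanceRatio, scope = scope),
            class = "ripScan")
}

#' @export
print.ripScan <- function(x, ...) {
  n <- nrow(x$calls)
  cat("ripScan of", n, "queries:",
      sum(x$calls$status == "pseudogene"), "pseudogene,",
      sum(x$calls$status == "functional-like"), "functional-like\n")
  invisible(x)
}

#' Dataset-level mutation and occurrence summary
#'
#' Averages the mutation frequencies over all called pseudogenes, breaks
#' the transition load down by ITS region, and reports the pseudogene
#' occurrence rate (individuals with at least one called pseudogene over
#' individuals tested) overall and per locality. Outgroup records are not
#' counted among the individuals tested.
#'
#' @param scan A `ripScan` result (or its `calls` data.frame).
#' @param x The [ItsSequenceSet] that was scanned.
#' @return List with `mutation` (mean `f_CtoT`, `f_GtoA`, `f_other` etc.
#'   across pseudogenes), `byRegion` (mean per-region transition counts),
#'   and `occurrence` (per-locality and overall `(all)` rows with
#'   `n_tested`, `n_carriers`, `rate`, `percent`).
#' @export
groupMutationSummary <- function(scan, x) {
  calls <- if (is.data.frame(scan)) scan else scan$calls
  ps <- if (nrow(calls)) calls[calls$status == "pseudogene", , drop = FALSE]
    else calls
  mutation <- data.frame(
    n_pseudogenes = nrow(ps),
    f_CtoT = if (nrow(ps)) mean(ps$f_CtoT) else NA_real_,
    f_GtoA = if (nrow(ps)) mean(ps$f_GtoA) else NA_real_,
    f_other = if (nrow(ps)) mean(ps$f_other) else NA_real_,
    f_CtoT_perC = if (nrow(ps)) mean(ps$f_CtoT_perC) else NA_real_,
    f_GtoA_perG = if (nrow(ps)) mean(ps$f_GtoA_perG) else NA_real_,
    mean_transitions = if (nrow(ps)) mean(ps$n_CtoT + ps$n_GtoA) else NA_real_,
    stringsAsFactors = FALSE)
  byRegion <- if (nrow(ps)) data.frame(
    region = c("ITS1", "5.8S", "ITS2"),
    mean_n_CtoT = c(mean(ps$n_CtoT_ITS1), mean(ps$n_CtoT_58S),
                    mean(ps$n_CtoT_ITS2)),
    mean_n_GtoA = c(mean(ps$n_GtoA_ITS1), mean(ps$n_GtoA_58S),
                    mean(ps$n_GtoA_ITS2)),
    stringsAsFactors = FALSE) else
    data.frame(region = character(), mean_n_CtoT = numeric(),
               mean_n_GtoA = numeric(), stringsAsFactors = FALSE)
  st <- seqStatus(x)
  tested <- unique(individualIds(x)[st != "outgroup"])
  loc <- individualIds(x)
  indLoc <- tapply(localities(x)[st != "outgroup"],
                   individualIds(x)[st != "outgroup"],
                   function(v) v[1])
  carriers <- unique(ps$individual_id)
  locLev <- sort(unique(unname(indLoc)))
  occRow <- function(l) {
    inL <- names(indLoc)[indLoc == l]
    data.frame(locality = l, n_tested = length(inL),
               n_carriers = sum(inL %in% carriers),
               stringsAsFactors = FALSE)
  }
  occurrence <- do.call(rbind, lapply(locLev, occRow))
  occurrence <- rbind(occurrence,
                      data.frame(locality = "(all)",
                                 n_tested = length(tested),
                                 n_carriers = length(carriers),
                                 stringsAsFactors = FALSE))
  occurrence$rate <- ifelse(occurrence$n_tested > 0,
                            occurrence$n_carriers / occurrence$n_tested,
                            NA_real_)
  occurrence$percent <- round(100 * occurrence$rate, 2)
  list(mutation = mutation, byRegion = byRegion, occurrence = occurrence)
}
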