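#' Collapse identical sequences into haplotypes
#'
#' Partitions the records into classes of identical sequences, the classic
#' haplotype definition for intragenomic rDNA polymorphism surveys. Two
#' records share a haplotype iff their compared residue strings are
#' identical under the declared normalization. Haplotype ids are assigned in
#' order of first occurrence (`h1`, `h2`, ...) and the representative of a
#' class is its first member, so the result is deterministic; the partition
#' itself is invariant under input order permutation.
#'
#' Normalization defaults: comparison is case-insensitive; alignment columns
#' gapped in every record of the input are ignored (so sets extracted from a
#' larger alignment still collapse correctly); ambiguity codes compare
#' literally (`N` differs from `A`), which is the strict reading of
#' "identical sequences" — both switches are exposed.
#'
#' @param x An [ItsSequenceSet] (records already trimmed/aligned to a common
#'   comparable scope, or `region` given).
#' @param region Optional integer `c(start, end)` restricting comparison to
#'   an interval (e.g. the amplified interval so that primer-internal
#'   GenBank copies and full-length clones are commensurable).
#' @param caseInsensitive Fold case before comparison (default `TRUE`).
#' @param dropSharedGapColumns Ignore columns gapped in all records
#'   (default `TRUE`).
#' @return A [HaplotypeTable].
#' @export
collapseHaplotypes <- function(x, region = NULL, caseInsensitive = TRUE,
                               dropSharedGapColumns = TRUE) {
  s <- as.character(x@seqs)
  ids <- names(s)
  if (!is.null(region)) {
    region <- as.integer(region)
    if (any(nchar(s) < region[2]))
      stop("region end ", region[2], " exceeds the length of record(s): ",
           paste(ids[nchar(s) < region[2]], collapse = ", "),
           "; align the records or adjust the region")
    s <- substr(s, region[1], region[2])
  }
  if (length(unique(nchar(s))) != 1)
    stop("records have unequal compared lengths (",
         paste(sort(unique(nchar(s))), collapse = ", "),
         "); supply an alignment or set `region`")
  if (caseInsensitive) s <- toupper(s)
  if (dropSharedGapColumns && any(grepl("-", s, fixed = TRUE))) {
    M <- do.call(rbind, strsplit(s, "", fixed = TRUE))
    keep <- colSums(M == "-") < nrow(M)
    s <- apply(M[, keep, drop = FALSE], 1, paste, collapse = "")
  }
  key <- factor(s, levels = unique(s))        # first-occurrence order
  hid <- paste0("h", as.integer(key))
  classes <- data.frame(
    haplotype_id = paste0("h", seq_len(nlevels(key))),
    size = as.integer(table(key)),
    representative = ids[match(levels(key), s)],
    members = vapply(levels(key),
                     function(k) paste(ids[s == k], collapse = ";"),
                     character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  new("HaplotypeTable", classes = classes,
      classMap = stats::setNames(hid, ids), nSequences = length(s))
}

#' Haplotype counts per individual
#'
#' @param table A [HaplotypeTable] built from the records in `x`.
#' @param x The [ItsSequenceSet] the table was built from (provides the
#'   record-to-individual mapping).
#' @return data.frame with `individual_id` and `n_haplotypes` (distinct
#'   haplotypes carried by that individual's records). Individuals with no
#'   records are simply absent.
#' @export
haplotypesPerIndividual <- function(table, x) {
  ids <- names(table@classMap)
  ind <- individualIds(x)[ids]
  if (length(ids) == 0)
    return(data.frame(individual_id = character(), n_haplotypes = integer(),
                      stringsAsFactors = FALSE))
  agg <- tapply(table@classMap, ind, function(h) length(unique(h)))
  data.frame(individual_id = names(agg), n_haplotypes = as.integer(agg),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Functional/pseudogene haplotype sharing between individuals
#'
#' For every pair of individuals carrying functional records, reports
#' whether they share a functional haplotype and whether they share any
#' pseudogene haplotype, the pattern that distinguishes shared ancestral RIP
#' events from independent ones. The summary tabulates the four
#' same/different x shared/disjoint combinations over pairs in which both
#' individuals carry at least one pseudogene.
#'
#' @param tableF [HaplotypeTable] of functional records.
#' @param tableP [HaplotypeTable] of pseudogene records (built on a
#'   consistent comparison region).
#' @param x The [ItsSequenceSet] both tables were derived from.
#' @return List with `pairs` (data.frame: `ind_a`, `ind_b`,
#'   `same_functional`, `shared_pseudogene`, `both_have_pseudogenes`) and
#'   `summary` (counts of the four combinations).
#' @export
haplotypeSharing <- function(tableF, tableP, x) {
  ind <- individualIds(x)
  fhap <- split(unname(tableF@classMap), ind[names(tableF@classMap)])
  phap <- split(unname(tableP@classMap), ind[names(tableP@classMap)])
  individuals <- sort(names(fhap))
  pairs <- list()
  if (length(individuals) >= 2) {
    cmb <- utils::combn(individuals, 2)
    pairs <- data.frame(
      ind_a = cmb[1, ], ind_b = cmb[2, ], stringsAsFactors = FALSE)
    pairs$same_functional <- mapply(function(a, b)
      length(intersect(fhap[[a]], fhap[[b]])) > 0, cmb[1, ], cmb[2, ])
    pairs$both_have_pseudogenes <- mapply(function(a, b)
      !is.null(phap[[a]]) && !is.null(phap[[b]]), cmb[1, ], cmb[2, ])
    pairs$shared_pseudogene <- mapply(function(a, b)
      length(intersect(phap[[a]], phap[[b]])) > 0, cmb[1, ], cmb[2, ])
  } else {
    pairs <- data.frame(ind_a = character(), ind_b = character(),
                        same_functional = logical(),
                        both_have_pseudogenes = logical(),
                        shared_pseudogene = logical(),
                        stringsAsFactors = FALSE)
  }
  both <- pairs[pairs$both_have_pseudogenes, , drop = FALSE]
  summary <- as.data.frame(table(
    functional = ifelse(both$same_functional, "same", "different"),
    pseudogene = ifelse(both$shared_pseudogene, "shared", "disjoint")),
    stringsAsFactors = FALSE)
  names(summary)[3] <- "n_pairs"
  list(pairs = pairs, summary = summary)
}

#' Write a HaplotypeTable to TSV (and representatives to FASTA)
#'
#' @param table A [HaplotypeTable].
#' @param x The source [ItsSequenceSet] (for representative sequences).
#' @param tsvPath Output TSV (`haplotype_id`, `size`, `representative`,
#'   `members`).
#' @param fastaPath Optional FASTA of one representative per haplotype.
#' @return Invisibly, `table`.
#' @export
writeHaplotypeTable <- function(table, x, tsvPath, fastaPath = NULL) {
  .writeTsv(table@classes, tsvPath)
  if (!is.null(fastaPath)) {
    reps <- x@seqs[table@classes$representative]
    names(reps) <- paste0(table@classes$haplotype_id, " ",
                          table@classes$representative)
    Biostrings::writeXStringSet(reps, fastaPath)
  }
  invisible(table)
}
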