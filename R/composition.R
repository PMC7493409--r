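#' GC content over unambiguous bases
#'
#' Computes (G + C) / (A + C + G + T), excluding gaps and IUPAC ambiguity
#' codes from both numerator and denominator. A sequence (or region) with no
#' unambiguous base yields `NA` (flagged undefined).
#'
#' @param x An [ItsSequenceSet], `DNAStringSet`, or character vector of
#'   sequences.
#' @param region Optional integer `c(start, end)` restricting the
#'   computation to a 1-based inclusive interval of each sequence.
#' @return Numeric vector of GC fractions in `[0, 1]` (named by record id
#'   where available).
#' @export
gcContent <- function(x, region = NULL) {
  s <- .asSeqChar(x)
  if (!is.null(region)) {
    region <- as.integer(region)
    if (any(nchar(s) < region[2]))
      stop("region end ", region[2], " exceeds sequence length")
    s <- substr(s, region[1], region[2])
  }
  cnt <- function(pat) nchar(gsub(pat, "", s))
  n_g <- nchar(s) - cnt("G")
  n_c <- nchar(s) - cnt("C")
  n_a <- nchar(s) - cnt("A")
  n_t <- nchar(s) - cnt("T")
  den <- n_a + n_c + n_g + n_t
  out <- ifelse(den == 0, NA_real_, (n_g + n_c) / den)
  names(out) <- names(s)
  out
}

#' Uncorrected p-distance between two aligned sequences
#'
#' Pairwise deletion: a site contributes only when both residues are
#' unambiguous bases (`A`, `C`, `G`, `T`); gaps and ambiguity codes are
#' dropped per pair. The distance is the fraction of differing sites among
#' the comparable sites.
#'
#' @param a,b Aligned sequences (character or `DNAString`) of equal length.
#' @return List with `distance` (NA when no comparable sites) and
#'   `comparable` (number of sites compared).
#' @export
pDistance <- function(a, b) {
  a <- .chars(a); b <- .chars(b)
  if (length(a) != length(b))
    stop("aligned lengths differ: ", length(a), " vs ", length(b))
  comp <- .isACGT(a) & .isACGT(b)
  n <- sum(comp)
  list(distance = if (n == 0) NA_real_ else sum(a[comp] != b[comp]) / n,
       comparable = as.integer(n))
}

#' Full pairwise p-distance matrix
#'
#' @param x An [ItsSequenceSet] (aligned: equal lengths), `DNAStringSet`, or
#'   named character vector.
#' @return Object of class `pDistanceMatrix`: list with `ids`, symmetric
#'   matrix `d` (zero diagonal, `NA` where no sites are comparable) and
#'   integer matrix `comparable`.
#' @export
pDistanceMatrix <- function(x) {
  s <- .asSeqChar(x)
  ids <- names(s)
  if (is.null(ids)) ids <- paste0("s", seq_along(s))
  if (length(unique(nchar(s))) != 1)
    stop("sequences must be aligned to equal length")
  n <- length(s)
  M <- do.call(rbind, strsplit(s, "", fixed = TRUE))
  ok <- .isACGT(M)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  cs <- matrix(0L, n, n, dimnames = list(ids, ids))
  diag(cs) <- as.integer(rowSums(ok))
  if (n > 1) for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    comp <- ok[i, ] & ok[j, ]
    m <- sum(comp)
    cs[i, j] <- cs[j, i] <- m
    d[i, j] <- d[j, i] <- if (m == 0) NA_real_ else
      sum(M[i, comp] != M[j, comp]) / m
  }
  structure(list(ids = ids, d = d, comparable = cs),
            class = "pDistanceMatrix")
}

#' @export
print.pDistanceMatrix <- function(x, ...) {
  cat("pDistanceMatrix over", length(x$ids), "sequences; mean off-diagonal",
      format(mean(x$d[upper.tri(x$d)], na.rm = TRUE), digits = 4), "\n")
  invisible(x)
}

#' Mean within-group p-distance
#'
#' Unweighted arithmetic mean of all pairwise p-distances among the group
#' members (the MEGA-style "average p-distance" with pairwise deletion).
#' Pairs with zero comparable sites are excluded from the mean and counted
#' in the `excluded` attribute.
#'
#' @param x An aligned [ItsSequenceSet], `DNAStringSet` or character vector.
#' @param ids Optional record ids defining the group (default: all).
#' @return Mean distance (numeric) with attributes `n_pairs` and `excluded`.
#' @export
meanWithinGroupDistance <- function(x, ids = NULL) {
  s <- .asSeqChar(x)
  if (!is.null(ids)) {
    miss <- setdiff(ids, names(s))
    if (length(miss)) stop("unknown id(s): ", paste(miss, collapse = ", "))
    s <- s[ids]
  }
  if (length(s) < 2) stop("need at least 2 group members")
  pm <- pDistanceMatrix(s)
  up <- pm$d[upper.tri(pm$d)]
  structure(mean(up, na.rm = TRUE), n_pairs = sum(!is.na(up)),
            excluded = sum(is.na(up)))
}

#' Per-sequence composition table
#'
#' @param x An [ItsSequenceSet].
#' @param region Optional `c(start, end)` interval.
#' @return data.frame with `id`, `status`, `length` (ungapped nt within the
#'   scope) and `gc` fraction.
#' @export
compositionTable <- function(x, region = NULL) {
  s <- as.character(x@seqs)
  if (!is.null(region)) s <- substr(s, region[1], region[2])
  data.frame(id = names(x@seqs), status = x@meta$status,
             length = nchar(.degap(s)), gc = gcContent(s),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Localize length variants against a reference sequence
#'
#' Globally aligns each record against the modal-length reference and
#' reports every insertion/deletion run with its reference coordinate, the
#' affected motif, and the ITS region it falls in. Gap placement within
#' homopolymers or repeats follows the deterministic alignment traceback, so
#' a planted indel is localized to within its repeat-equivalence window.
#'
#' @param x An [ItsSequenceSet] of (ungapped) records to screen.
#' @param reference The reference record: an id present in `x` or a
#'   character sequence.
#' @param map Optional [RegionMap] on the reference used to label variants.
#' @param all Compare all records (default: only those whose length differs
#'   from the reference).
#' @return data.frame with columns `id`, `type` (`deletion`/`insertion`),
#'   `ref_start`, `length`, `motif`, `region`.
#' @export
lengthVariants <- function(x, reference, map = NULL, all = FALSE) {
  refseq <- if (is.character(reference) && reference %in% names(x@seqs)) {
    as.character(x@seqs[[match(reference, names(x@seqs))]])
  } else as.character(reference)
  refseq <- .degap(refseq)
  out <- list()
  for (id in names(x@seqs)) {
    s <- .degap(as.character(x@seqs[[match(id, names(x@seqs))]]))
    if (!all && nchar(s) == nchar(refseq)) next
    if (identical(s, refseq)) next
    aln <- .globalAlign(s, refseq)
    q <- .chars(aln$q); r <- .chars(aln$r)
    refpos <- cumsum(r != "-")
    gapq <- rle(q == "-")
    ends <- cumsum(gapq$lengths)
    starts <- ends - gapq$lengths + 1L
    for (k in which(gapq$values)) {        # deletions in the query
      i0 <- starts[k]; i1 <- ends[k]
      out[[length(out) + 1L]] <- data.frame(
        id = id, type = "deletion", ref_start = refpos[i0],
        length = i1 - i0 + 1L,
        motif = paste(r[i0:i1], collapse = ""),
        stringsAsFactors = FALSE)
    }
    gapr <- rle(r == "-")
    ends <- cumsum(gapr$lengths)
    starts <- ends - gapr$lengths + 1L
    for (k in which(gapr$values)) {        # insertions in the query
      i0 <- starts[k]; i1 <- ends[k]
      out[[length(out) + 1L]] <- data.frame(
        id = id, type = "insertion",
        ref_start = if (i0 > 1) refpos[i0 - 1L] else 0L,
        length = i1 - i0 + 1L,
        motif = paste(q[i0:i1], collapse = ""),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(id = character(), type = character(),
                      ref_start = integer(), length = integer(),
                      motif = character(), region = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res$region <- if (is.null(map)) NA_character_ else
    regionOfPosition(map, res$ref_start)
  res
}

#' Write a p-distance matrix to TSV and PHYLIP lower-triangle formats
#'
#' @param pm A `pDistanceMatrix`.
#' @param tsvPath,phylipPath Output paths (either may be `NULL`).
#' @return Invisibly, `pm`.
#' @export
writeDistanceMatrix <- function(pm, tsvPath = NULL, phylipPath = NULL) {
  if (!is.null(tsvPath)) {
    df <- data.frame(id = pm$ids, as.data.frame(pm$d), check.names = FALSE)
    .writeTsv(df, tsvPath)
  }
  if (!is.null(phylipPath)) {
    con <- file(phylipPath, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", length(pm$ids)), con)
    for (i in seq_along(pm$ids)) {
      row <- if (i == 1) "" else
        paste(sprintf("%.6f", pm$d[i, seq_len(i - 1)]), collapse = " ")
      writeLines(paste(formatC(pm$ids[i], width = -12), row), con)
    }
  }
  invisible(pm)
}
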