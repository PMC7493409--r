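#' @importFrom Biostrings DNAStringSet readBStringSet writeXStringSet width
NULL

.normalizeResidues <- function(x, ids) {
  x <- toupper(x)
  x <- gsub("U", "T", x, fixed = TRUE)
  ok <- paste0("ACGTRYSWKMBDHVN-")
  bad <- regexpr(sprintf("[^%s]", ok), x)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop("non-IUPAC character '", substr(x[i], bad[i], bad[i]),
         "' in record '", ids[i], "' at position ", bad[i])
  }
  x
}

.emptyMeta <- function(ids) {
  S4Vectors::DataFrame(individual_id = ids, locality = "",
                       source = "specimen", status = "candidate",
                       row.names = NULL)
}

#' Construct an ItsSequenceSet
#'
#' @param seqs Named character vector or `DNAStringSet` of DNA sequences
#'   (IUPAC codes; `U` is mapped to `T`, case is folded to upper).
#' @param meta Optional data.frame/`DataFrame` with columns `individual_id`,
#'   `locality`, `source`, `status` (and optionally `truth_status`), one row
#'   per sequence in order, or keyed by an `id` column. Missing metadata
#'   defaults to status `candidate`, the record id as `individual_id`, and
#'   source `specimen`.
#' @return An [ItsSequenceSet].
#' @export
itsSequenceSet <- function(seqs, meta = NULL) {
  if (is(seqs, "XStringSet")) seqs <- as.character(seqs)
  ids <- names(seqs)
  if (is.null(ids)) stop("sequences must be named with record ids")
  if (anyDuplicated(ids))
    stop("duplicate record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- .normalizeResidues(seqs, ids)
  if (is.null(meta)) {
    meta <- .emptyMeta(ids)
  } else {
    meta <- as(as.data.frame(meta), "DataFrame")
    if ("id" %in% colnames(meta)) {
      full <- .emptyMeta(ids)
      hit <- match(ids, meta$id)
      for (cl in setdiff(colnames(meta), "id")) {
        got <- !is.na(hit)
        full[[cl]][got] <- meta[[cl]][hit[got]]
      }
      meta <- full
    }
  }
  for (cl in c("individual_id", "locality", "source", "status"))
    if (is.null(meta[[cl]])) meta[[cl]] <- .emptyMeta(ids)[[cl]]
  new("ItsSequenceSet", seqs = DNAStringSet(stats::setNames(seqs, ids)),
      meta = meta)
}

#' Read ITS sequences from FASTA with sidecar metadata
#'
#' Sequences are upper-cased and `U` converted to `T` on ingest; any
#' character outside the IUPAC nucleotide alphabet (plus `-`) is rejected
#' with the offending record and position named. Metadata is supplied as a
#' sidecar TSV (columns `id`, `individual_id`, `locality`, `status`,
#' optionally `source`) rather than parsed from headers; records absent from
#' the metadata default to status `candidate` with empty locality.
#' Alternatively `headerPattern` (a PCRE with named capture groups
#' `individual`, `locality` and/or `status`) extracts metadata from the
#' FASTA headers themselves.
#'
#' @param path FASTA file.
#' @param metadata Optional path to a metadata TSV, or a data.frame.
#' @param headerPattern Optional Perl regex with named capture groups used as
#'   a fallback metadata source when no sidecar table is given.
#' @return An [ItsSequenceSet].
#' @export
readItsFasta <- function(path, metadata = NULL, headerPattern = NULL) {
  raw <- readBStringSet(path)
  if (length(raw) == 0) stop("no sequences found in ", path)
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids))
    stop("duplicate record id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- stats::setNames(as.character(raw), ids)
  if (is.character(metadata) && length(metadata) == 1)
    metadata <- utils::read.delim(metadata, stringsAsFactors = FALSE,
                                  colClasses = "character")
  if (is.null(metadata) && !is.null(headerPattern)) {
    m <- regexpr(headerPattern, names(raw), perl = TRUE)
    metadata <- data.frame(id = ids, stringsAsFactors = FALSE)
    for (gp in attr(m, "capture.names")[attr(m, "capture.names") != ""]) {
      st <- attr(m, "capture.start")[, gp]
      ln <- attr(m, "capture.length")[, gp]
      val <- ifelse(st > 0, substr(names(raw), st, st + ln - 1L), "")
      metadata[[if (gp == "individual") "individual_id" else gp]] <- val
    }
  }
  itsSequenceSet(seqs, metadata)
}

#' Write an ItsSequenceSet to FASTA (and optionally its metadata to TSV)
#'
#' @param x An [ItsSequenceSet].
#' @param path Output FASTA path.
#' @param metadataPath Optional TSV path for the metadata sidecar.
#' @return Invisibly, `path`.
#' @export
writeItsFasta <- function(x, path, metadataPath = NULL) {
  writeXStringSet(x@seqs, path)
  if (!is.null(metadataPath)) {
    df <- cbind(id = names(x@seqs), as.data.frame(x@meta))
    utils::write.table(df, metadataPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a multiple alignment (aligned FASTA or sequential NEXUS)
#'
#' Aligned FASTA is read directly; files whose first non-blank characters
#' are `#NEXUS` are parsed read-only with [ape::read.nexus.data()] (relaxed
#' sequential/interleaved NEXUS). Column regions default to a single region
#' guess of all-`flank` unless a [RegionMap] plus flank widths are given via
#' [alignmentFromMap()] afterwards, or `columnRegion` is supplied.
#'
#' @param path Alignment file.
#' @param metadata Optional metadata table or TSV path (see [readItsFasta()]).
#' @param columnRegion Optional character vector of per-column region labels.
#' @return An [ItsAlignment].
#' @export
readAlignment <- function(path, metadata = NULL, columnRegion = NULL) {
  first <- toupper(trimws(readLines(path, n = 1)))
  if (startsWith(first, "#NEXUS")) {
    lst <- ape::read.nexus.data(path)
    seqs <- vapply(lst, function(ch) paste(ch, collapse = ""), character(1))
    x <- itsSequenceSet(seqs, metadata)
  } else {
    x <- readItsFasta(path, metadata)
  }
  w <- unique(width(x@seqs))
  if (length(w) != 1)
    stop("sequences are not aligned: lengths ", paste(w, collapse = ", "))
  if (is.null(columnRegion)) columnRegion <- rep("flank", w)
  new("ItsAlignment", seqs = x@seqs, meta = x@meta,
      columnRegion = columnRegion)
}

#' Label alignment columns from a RegionMap
#'
#' Maps ungapped reference coordinates to alignment columns using a chosen
#' reference row, labelling columns `ITS1`/`5.8S`/`ITS2` and everything
#' outside the map `flank`. Columns where the reference row is gapped take
#' the label of the previous reference position's region.
#'
#' @param x An [ItsSequenceSet] or [ItsAlignment] with equal-length rows.
#' @param map A [RegionMap] on the ungapped reference coordinates.
#' @param reference Record id of the alignment row carrying the map
#'   (default: the first row).
#' @return An [ItsAlignment].
#' @export
alignmentFromMap <- function(x, map, reference = seqIds(x)[1]) {
  w <- unique(width(x@seqs))
  if (length(w) != 1) stop("sequences are not aligned")
  refch <- strsplit(as.character(x@seqs[[match(reference, names(x@seqs))]]),
                    "")[[1]]
  pos <- cumsum(refch != "-")
  pos[pos == 0] <- 1L
  lab <- regionOfPosition(map, pos)
  new("ItsAlignment", seqs = x@seqs, meta = x@meta, columnRegion = lab)
}

#' Remove flanking rDNA columns from an alignment
#'
#' Drops every column labelled `flank` (the small/large-subunit rDNA
#' flanks), keeping only ITS1, 5.8S and ITS2 columns. Record order is
#' preserved and the operation is idempotent.
#'
#' @param alignment An [ItsAlignment].
#' @return The trimmed [ItsAlignment].
#' @export
trimFlanks <- function(alignment) {
  stopifnot(is(alignment, "ItsAlignment"))
  keep <- alignment@columnRegion != "flank"
  if (!any(keep)) stop("alignment has no ITS columns after trimming")
  if (all(keep)) return(alignment)
  kept <- IRanges::IRanges(start = which(keep), width = 1L)
  seqs <- DNAStringSet(vapply(seq_along(alignment@seqs), function(i) {
    paste(strsplit(as.character(alignment@seqs[[i]]), "")[[1]][keep],
          collapse = "")
  }, character(1)))
  names(seqs) <- names(alignment@seqs)
  new("ItsAlignment", seqs = seqs, meta = alignment@meta,
      columnRegion = alignment@columnRegion[keep])
}

# ---- region maps -----------------------------------------------------------

#' Construct a RegionMap
#'
#' @param its1,r5_8s,its2,amplified Numeric vectors `c(start, end)`, 1-based
#'   inclusive on the ungapped reference sequence.
#' @return A [RegionMap].
#' @export
regionMap <- function(its1, r5_8s, its2, amplified) {
  new("RegionMap", its1 = as.integer(its1), r5_8s = as.integer(r5_8s),
      its2 = as.integer(its2), amplified = as.integer(amplified))
}

#' Default region layout for the 562-bp reference ITS
#'
#' The subregion boundaries are not universal constants, so the map is user
#' configurable; this default follows the 562-nt functional reference layout
#' used throughout the package: ITS1 = 1-218, 5.8S = 219-376, ITS2 =
#' 377-562. The "amplified" interval 96-512 (417 nt) is the part covered by
#' the pseudogene-specific internal primer pair, which misses 95 bp of ITS1
#' and 50 bp of ITS2.
#'
#' @return A [RegionMap].
#' @export
defaultRegionMap <- function() {
  regionMap(its1 = c(1, 218), r5_8s = c(219, 376), its2 = c(377, 562),
            amplified = c(96, 512))
}

#' Read a RegionMap from YAML
#'
#' Expects top-level keys `its1`, `r5_8s`, `its2`, `amplified`, each a
#' two-element `[start, end]` list.
#'
#' @param path YAML file.
#' @return A [RegionMap].
#' @export
readRegionMap <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("its1", "r5_8s", "its2", "amplified")
  miss <- setdiff(need, names(y))
  if (length(miss))
    stop("region YAML lacks key(s): ", paste(miss, collapse = ", "))
  regionMap(unlist(y$its1), unlist(y$r5_8s), unlist(y$its2),
            unlist(y$amplified))
}

#' Write a RegionMap to YAML
#' @param map A [RegionMap].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeRegionMap <- function(map, path) {
  yaml::write_yaml(list(its1 = as.integer(map@its1),
                        r5_8s = as.integer(map@r5_8s),
                        its2 = as.integer(map@its2),
                        amplified = as.integer(map@amplified)), path)
  invisible(path)
}

#' Region label of ungapped reference positions
#'
#' @param map A [RegionMap].
#' @param positions Integer positions (1-based, ungapped).
#' @return Character vector of `ITS1`/`5.8S`/`ITS2`/`flank` labels.
#' @export
regionOfPosition <- function(map, positions) {
  out <- rep("flank", length(positions))
  out[positions >= map@its1[1] & positions <= map@its1[2]] <- "ITS1"
  out[positions >= map@r5_8s[1] & positions <= map@r5_8s[2]] <- "5.8S"
  out[positions >= map@its2[1] & positions <= map@its2[2]] <- "ITS2"
  out
}

#' Region lengths of a RegionMap
#'
#' @param map A [RegionMap].
#' @return Named integer vector with the ITS1/5.8S/ITS2 lengths, their
#'   `total`, and the `amplified` interval length.
#' @export
regionLengths <- function(map) {
  out <- c(ITS1 = diff(map@its1) + 1L, `5.8S` = diff(map@r5_8s) + 1L,
           ITS2 = diff(map@its2) + 1L)
  c(out, total = sum(out), amplified = diff(map@amplified) + 1L)
}

#' Annotate a record (or set) with a RegionMap
#'
#' Validates that the map fits within the ungapped sequence length and
#' returns the per-region coordinate table for the record.
#'
#' @param x An [ItsSequenceSet] (the map must fit every record) or a single
#'   sequence (character).
#' @param map A [RegionMap].
#' @return A data.frame with columns `region`, `start`, `end`, `length`.
#' @export
annotateRegions <- function(x, map) {
  len <- if (is(x, "ItsSequenceSet")) {
    min(width(DNAStringSet(gsub("-", "", as.character(x@seqs)))))
  } else {
    nchar(gsub("-", "", as.character(x)[1]))
  }
  hi <- max(map@its2[2], map@amplified[2])
  if (hi > len)
    stop("region map extends to position ", hi,
         " but the (shortest) sequence has only ", len, " nt")
  data.frame(
    region = c("ITS1", "5.8S", "ITS2", "amplified"),
    start = c(map@its1[1], map@r5_8s[1], map@its2[1], map@amplified[1]),
    end = c(map@its1[2], map@r5_8s[2], map@its2[2], map@amplified[2]),
    length = c(diff(map@its1), diff(map@r5_8s), diff(map@its2),
               diff(map@amplified)) + 1L,
    stringsAsFactors = FALSE)
}

#' Extract a coordinate interval from every record
#'
#' Convenience used to restrict comparisons to the amplified interval:
#' returns the subsequences `start..end` (1-based inclusive, ungapped
#' coordinates of each record).
#'
#' @param x An [ItsSequenceSet].
#' @param interval Integer `c(start, end)`.
#' @return An [ItsSequenceSet] of the extracted subsequences.
#' @export
extractInterval <- function(x, interval) {
  interval <- as.integer(interval)
  if (any(width(x@seqs) < interval[2]))
    stop("interval end ", interval[2], " exceeds the length of record(s): ",
         paste(names(x@seqs)[width(x@seqs) < interval[2]], collapse = ", "))
  seqs <- Biostrings::subseq(x@seqs, start = interval[1], end = interval[2])
  initialize(x, seqs = seqs, meta = x@meta)
}
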