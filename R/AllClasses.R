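#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

.STATUS_LEVELS <- c("functional", "candidate", "pseudogene", "outgroup")
.SOURCE_LEVELS <- c("specimen", "culture", "genbank", "simulated")
.REGION_LEVELS <- c("ITS1", "5.8S", "ITS2", "flank")

#' RIP dinucleotide context classes
#'
#' The four mutation context classes used throughout the package, in the
#' conventional RIPCAL order, plus `"nonRIP"` for substitutions that are not
#' G:C -> A:T transitions (or transitions at sequence edges where no flanking
#' neighbour exists).
#'
#' * `CpA<->TpA` — C->T with a 3' A on the reference strand, or G->A with a
#'   5' T (TpG on the reference strand reads CpA on the complement).
#' * `CpC<->TpC` — C->T with 3' C / G->A with 5' G.
#' * `CpG<->TpG` — C->T with 3' G / G->A with 5' C.
#' * `CpT<->TpT` — C->T with 3' T / G->A with 5' A.
#'
#' @return Character vector of the five class labels.
#' @export
contextClasses <- function() {
  c("CpA<->TpA", "CpC<->TpC", "CpG<->TpG", "CpT<->TpT", "nonRIP")
}

#' Container for ITS sequence records and their metadata
#'
#' An `ItsSequenceSet` couples a [Biostrings::DNAStringSet] (one entry per
#' ITS copy; names are the record ids) with per-record metadata: the
#' individual each copy was amplified from, its sampling locality, its
#' provenance and its functional status. Simulated data additionally carry a
#' `truth_status` column holding the generator's ground truth, kept separate
#' from `status` so that recovery experiments never leak the answer.
#'
#' @slot seqs A `DNAStringSet`; names are unique record ids.
#' @slot meta A `DataFrame` with columns `individual_id`, `locality`,
#'   `source`, `status` and optionally `truth_status`, one row per sequence.
#'
#' @aliases ItsSequenceSet
#' @exportClass ItsSequenceSet
setClass("ItsSequenceSet",
  representation(seqs = "DNAStringSet", meta = "DataFrame"))

setValidity("ItsSequenceSet", function(object) {
  ids <- names(object@seqs)
  msg <- character()
  if (is.null(ids) || any(ids == ""))
    msg <- c(msg, "all sequences must be named with record ids")
  if (anyDuplicated(ids))
    msg <- c(msg, paste0("duplicate record id(s): ",
                         paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (any(Biostrings::width(object@seqs) == 0L))
    msg <- c(msg, "empty sequences are not allowed")
  if (nrow(object@meta) != length(object@seqs))
    msg <- c(msg, "metadata must have one row per sequence")
  need <- c("individual_id", "locality", "source", "status")
  miss <- setdiff(need, colnames(object@meta))
  if (length(miss))
    msg <- c(msg, paste0("metadata lacks column(s): ", paste(miss, collapse = ", ")))
  if ("status" %in% colnames(object@meta) &&
      !all(object@meta$status %in% .STATUS_LEVELS))
    msg <- c(msg, paste0("status must be one of: ", paste(.STATUS_LEVELS, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Multiple alignment of ITS records with per-column region labels
#'
#' An `ItsAlignment` is an [ItsSequenceSet] whose sequences all have equal
#' (gapped) length, plus a region label (`ITS1`, `5.8S`, `ITS2` or `flank`)
#' for every alignment column. Flanking small/large-subunit rDNA columns are
#' labelled `flank` and can be dropped with [trimFlanks()].
#'
#' @slot columnRegion Character vector, one label per alignment column.
#' @aliases ItsAlignment
#' @exportClass ItsAlignment
setClass("ItsAlignment", contains = "ItsSequenceSet",
  representation(columnRegion = "character"))

setValidity("ItsAlignment", function(object) {
  w <- unique(Biostrings::width(object@seqs))
  msg <- character()
  if (length(w) > 1)
    msg <- c(msg, "aligned sequences must all have the same length")
  if (length(w) == 1 && length(object@columnRegion) != w)
    msg <- c(msg, "columnRegion must have one label per alignment column")
  if (!all(object@columnRegion %in% .REGION_LEVELS))
    msg <- c(msg, paste0("column regions must be one of: ",
                         paste(.REGION_LEVELS, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' ITS1 / 5.8S / ITS2 region coordinates
#'
#' Coordinates of the three ITS subregions, and of the sub-interval covered
#' by the pseudogene-specific primer pair ("amplified"), on an ungapped
#' reference sequence. All coordinates are 1-based and inclusive.
#'
#' @slot its1,r5_8s,its2 Integer vectors `c(start, end)`.
#' @slot amplified Integer vector `c(start, end)`, contained in the union of
#'   the three regions.
#' @aliases RegionMap
#' @exportClass RegionMap
setClass("RegionMap",
  representation(its1 = "integer", r5_8s = "integer", its2 = "integer",
                 amplified = "integer"))

setValidity("RegionMap", function(object) {
  iv <- list(its1 = object@its1, r5_8s = object@r5_8s, its2 = object@its2,
             amplified = object@amplified)
  msg <- character()
  for (nm in names(iv)) {
    v <- iv[[nm]]
    if (length(v) != 2L || any(is.na(v)) || v[1] < 1L || v[2] < v[1])
      msg <- c(msg, paste0(nm, " must be c(start, end) with 1 <= start <= end"))
  }
  if (!length(msg)) {
    if (object@r5_8s[1] <= object@its1[2] || object@its2[1] <= object@r5_8s[2])
      msg <- c(msg, "regions must be ordered ITS1 < 5.8S < ITS2 without overlap")
    if (object@amplified[1] < object@its1[1] || object@amplified[2] > object@its2[2])
      msg <- c(msg, "amplified interval must lie within ITS1..ITS2")
  }
  if (length(msg)) msg else TRUE
})

#' Partition of a sequence set into identical-sequence haplotypes
#'
#' @slot classes A data.frame with columns `haplotype_id`, `size`,
#'   `representative` (id of the first member) and `members`
#'   (semicolon-joined record ids).
#' @slot classMap Named character vector mapping every record id to its
#'   haplotype id.
#' @slot nSequences Number of input sequences.
#' @aliases HaplotypeTable
#' @exportClass HaplotypeTable
setClass("HaplotypeTable",
  representation(classes = "data.frame", classMap = "character",
                 nSequences = "integer"))

setValidity("HaplotypeTable", function(object) {
  msg <- character()
  if (sum(object@classes$size) != object@nSequences)
    msg <- c(msg, "class sizes must sum to the number of sequences")
  if (length(object@classMap) != object@nSequences)
    msg <- c(msg, "classMap must assign every sequence to exactly one class")
  if (!all(object@classMap %in% object@classes$haplotype_id))
    msg <- c(msg, "classMap refers to unknown haplotype ids")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ItsSequenceSet", function(object) {
  st <- table(factor(object@meta$status, levels = .STATUS_LEVELS))
  cat("ItsSequenceSet with", length(object@seqs), "records (",
      paste(paste0(names(st), ": ", as.integer(st)), collapse = ", "), ")\n")
  cat("  individuals:", length(unique(object@meta$individual_id)),
      " localities:", length(unique(object@meta$locality[object@meta$locality != ""])), "\n")
})

setMethod("show", "ItsAlignment", function(object) {
  cat("ItsAlignment with", length(object@seqs), "sequences x",
      Biostrings::width(object@seqs)[1], "columns\n")
  tr <- table(factor(object@columnRegion, levels = .REGION_LEVELS))
  cat("  columns by region:",
      paste(paste0(names(tr), "=", as.integer(tr)), collapse = " "), "\n")
})

setMethod("show", "RegionMap", function(object) {
  cat("RegionMap (1-based, inclusive)\n")
  cat(sprintf("  ITS1      %4d..%-4d (%d nt)\n", object@its1[1], object@its1[2],
              diff(object@its1) + 1L))
  cat(sprintf("  5.8S      %4d..%-4d (%d nt)\n", object@r5_8s[1], object@r5_8s[2],
              diff(object@r5_8s) + 1L))
  cat(sprintf("  ITS2      %4d..%-4d (%d nt)\n", object@its2[1], object@its2[2],
              diff(object@its2) + 1L))
  cat(sprintf("  amplified %4d..%-4d (%d nt)\n", object@amplified[1],
              object@amplified[2], diff(object@amplified) + 1L))
})

setMethod("show", "HaplotypeTable", function(object) {
  cat("HaplotypeTable:", nrow(object@classes), "haplotypes from",
      object@nSequences, "sequences\n")
  sz <- sort(object@classes$size, decreasing = TRUE)
  cat("  class sizes:", paste(utils::head(sz, 10), collapse = " "),
      if (length(sz) > 10) "..." else "", "\n")
})

#' @describeIn ItsSequenceSet Number of records.
#' @param x An `ItsSequenceSet`.
#' @export
setMethod("length", "ItsSequenceSet", function(x) length(x@seqs))

#' Subset an ItsSequenceSet by index, id or logical mask
#'
#' @param x An `ItsSequenceSet`.
#' @param i Numeric/logical index or character record ids.
#' @param j,...,drop Ignored.
#' @return An `ItsSequenceSet` with the selected records.
#' @export
setMethod("[", "ItsSequenceSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) {
    miss <- setdiff(i, names(x@seqs))
    if (length(miss))
      stop("unknown record id(s): ", paste(miss, collapse = ", "))
    i <- match(i, names(x@seqs))
  }
  initialize(x, seqs = x@seqs[i], meta = x@meta[i, , drop = FALSE])
})

setMethod("[", "ItsAlignment", function(x, i, j, ..., drop = FALSE) {
  y <- callNextMethod()
  new("ItsAlignment", seqs = y@seqs, meta = y@meta,
      columnRegion = x@columnRegion)
})

# ---- accessors -------------------------------------------------------------

#' Accessors for ItsSequenceSet components
#'
#' `seqIds` returns the record ids, `sequences` the underlying
#' `DNAStringSet`, `seqMeta` the metadata `DataFrame`, `seqStatus` /
#' `individualIds` / `localities` the corresponding metadata columns (named
#' by record id), and `columnRegions` the per-column region labels of an
#' alignment.
#'
#' @param x An `ItsSequenceSet` (or `ItsAlignment` for `columnRegions`).
#' @return See the individual descriptions.
#' @name its-accessors
NULL

#' @rdname its-accessors
#' @export
seqIds <- function(x) names(x@seqs)

#' @rdname its-accessors
#' @export
sequences <- function(x) x@seqs

#' @rdname its-accessors
#' @export
seqMeta <- function(x) x@meta

#' @rdname its-accessors
#' @export
seqStatus <- function(x) stats::setNames(x@meta$status, names(x@seqs))

#' @rdname its-accessors
#' @export
individualIds <- function(x) stats::setNames(x@meta$individual_id, names(x@seqs))

#' @rdname its-accessors
#' @export
localities <- function(x) stats::setNames(x@meta$locality, names(x@seqs))

#' @rdname its-accessors
#' @export
columnRegions <- function(x) {
  stopifnot(is(x, "ItsAlignment"))
  x@columnRegion
}

#' Replace the status column of an ItsSequenceSet
#'
#' @param x An `ItsSequenceSet`.
#' @param value Character vector of statuses (recycled if length 1), each one
#'   of `functional`, `candidate`, `pseudogene`, `outgroup`.
#' @return The modified object.
#' @export
`seqStatus<-` <- function(x, value) {
  x@meta$status <- rep_len(value, length(x@seqs))
  validObject(x)
  x
}

#' Accessors for HaplotypeTable components
#'
#' `haplotypeClasses` returns the class table (one row per haplotype),
#' `classMap` the record-id to haplotype-id mapping, `nHaplotypes` the
#' number of classes.
#'
#' @param x A `HaplotypeTable`.
#' @name haplotype-accessors
NULL

#' @rdname haplotype-accessors
#' @export
haplotypeClasses <- function(x) x@classes

#' @rdname haplotype-accessors
#' @export
classMap <- function(x) x@classMap

#' @rdname haplotype-accessors
#' @export
nHaplotypes <- function(x) nrow(x@classes)
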