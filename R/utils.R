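.degap <- function(s) gsub("-", "", s, fixed = TRUE)

.chars <- function(s) strsplit(as.character(s), "", fixed = TRUE)[[1]]

# Deterministic global (Needleman-Wunsch) alignment of two ungapped DNA
# strings: match +1, mismatch -1, affine gap penalty open 5 + 2 per base.
.globalAlign <- function(query, reference) {
  query <- .degap(as.character(query))
  reference <- .degap(as.character(reference))
  if (nchar(query) == 0 || nchar(reference) == 0)
    stop("cannot align an empty sequence")
  if (identical(query, reference))
    return(list(q = query, r = reference, score = nchar(query)))
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  pwa <- Biostrings::pairwiseAlignment(
    pattern = query, subject = reference, type = "global",
    substitutionMatrix = sub, gapOpening = 5, gapExtension = 2)
  list(q = as.character(Biostrings::alignedPattern(pwa)),
       r = as.character(Biostrings::alignedSubject(pwa)),
       score = Biostrings::score(pwa))
}

# Largest-remainder apportionment of `total` into parts proportional to
# `weights` (used by the deterministic carrier-assignment mode).
.apportion <- function(total, weights) {
  if (total == 0 || sum(weights) == 0) return(rep(0L, length(weights)))
  quota <- total * weights / sum(weights)
  out <- floor(quota)
  rem <- total - sum(out)
  if (rem > 0) {
    take <- order(quota - out, decreasing = TRUE)[seq_len(rem)]
    out[take] <- out[take] + 1L
  }
  as.integer(out)
}

.isACGT <- function(ch) ch == "A" | ch == "C" | ch == "G" | ch == "T"

# sequences as a named character vector, whatever the container
.asSeqChar <- function(x) {
  if (is(x, "ItsSequenceSet")) return(as.character(x@seqs))
  nm <- names(x)
  out <- as.character(x)
  names(out) <- nm
  out
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
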