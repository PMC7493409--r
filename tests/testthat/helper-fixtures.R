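# In-code fixtures shared across test files. Everything is generated
# programmatically; no binary data.

# A tiny sequence set with explicit metadata.
toySet <- function() {
  itsSequenceSet(
    c(a1 = "ACGTACGT", a2 = "ACGTACGT", b1 = "ACGTACGA", c1 = "TTTTACGT"),
    data.frame(id = c("a1", "a2", "b1", "c1"),
               individual_id = c("indA", "indA", "indB", "indC"),
               locality = c("L1", "L1", "L2", "L2"),
               status = c("functional", "candidate", "functional",
                          "outgroup"),
               stringsAsFactors = FALSE))
}

# Random ungapped DNA string.
randSeq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Brute-force all-pairs identity partition (the haplotype oracle).
bruteHaplotypePartition <- function(seqs) {
  n <- length(seqs)
  cls <- integer(n)
  nxt <- 0L
  for (i in seq_len(n)) {
    if (cls[i] > 0) next
    nxt <- nxt + 1L
    cls[i] <- nxt
    if (i < n) for (j in (i + 1):n) {
      if (cls[j] == 0 && identical(seqs[[i]], seqs[[j]])) cls[j] <- nxt
    }
  }
  cls
}

# Write a FASTA file from a named character vector; returns the path.
writeFastaFixture <- function(seqs, path = tempfile(fileext = ".fasta")) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) writeLines(c(paste0(">", nm), seqs[[nm]]), con)
  path
}

# Small simulated population (reduced sizes for unit-test speed).
smallSim <- function(seed, nInd = 30, occurrence = 0.4, severity = 0.2,
                     sharedOrigin = TRUE, ...) {
  loc <- data.frame(locality = c("north", "south"),
                    n = c(ceiling(nInd / 2), floor(nInd / 2)),
                    occurrence = occurrence, stringsAsFactors = FALSE)
  simulatePopulation(ripSimConfig(
    seed = seed, nIndividuals = nInd, localities = loc,
    nFunctionalHaplotypes = 5, severity = severity,
    sharedOrigin = sharedOrigin, ...))
}
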