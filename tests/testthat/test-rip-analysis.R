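test_that("pairAlign is exact on identical input and excludes gap blocks", {
  a <- pairAlign(c(q = "ACGTACGT"), c(r = "ACGTACGT"))
  expect_equal(a$q, a$r)
  expect_equal(nrow(classifySubstitutions(a)), 0L)

  set.seed(61)
  ref <- randSeq(200, gc = 0.5)
  ch <- strsplit(ref, "")[[1]]
  cpos <- sample(which(ch == "C"), 5)
  ch[cpos] <- "T"
  ev <- classifySubstitutions(pairAlign(paste(ch, collapse = ""), ref))
  expect_equal(nrow(ev), 5L)
  expect_setequal(ev$position, cpos)
  expect_true(all(ev$type == "C->T"))

  # a deletion is excluded from substitution calling
  qdel <- paste0(substr(ref, 1, 99), substr(ref, 110, 200))
  evd <- classifySubstitutions(pairAlign(qdel, ref))
  expect_equal(nrow(evd), 0L)
})

test_that("substitutions are classified by reference-strand dinucleotide context", {
  ev <- classifySubstitutions(list(q = "ATAG", r = "ACAG"))
  expect_equal(ev$type, "C->T")
  expect_equal(ev$context_class, "CpA<->TpA")

  ev <- classifySubstitutions(list(q = "TTAA", r = "TTGA"))
  expect_equal(ev$type, "G->A")
  expect_equal(ev$context_class, "CpA<->TpA")  # TpG on ref = CpA on complement

  ev <- classifySubstitutions(list(q = "AAGA", r = "AAAA"))
  expect_equal(ev$type, "other")
  expect_equal(ev$context_class, "nonRIP")

  # edge positions have no neighbour and are classed nonRIP
  ev <- classifySubstitutions(list(q = "ACGA", r = "GCGA"))
  expect_equal(ev$type, "G->A")
  expect_equal(ev$context_class, "nonRIP")
  ev <- classifySubstitutions(list(q = "ACGT", r = "ACGC"))
  expect_equal(ev$type, "C->T")
  expect_equal(ev$context_class, "nonRIP")

  # the full dinucleotide rule table
  for (nb in c("A", "C", "G", "T")) {
    cls <- classifySubstitutions(list(q = paste0("AT", nb, "A"),
                                      r = paste0("AC", nb, "A")))$context_class
    expect_equal(cls, switch(nb, A = "CpA<->TpA", C = "CpC<->TpC",
                             G = "CpG<->TpG", T = "CpT<->TpT"))
    cls <- classifySubstitutions(list(q = paste0("A", nb, "AA"),
                                      r = paste0("A", nb, "GA")))$context_class
    expect_equal(cls, switch(nb, T = "CpA<->TpA", G = "CpC<->TpC",
                             C = "CpG<->TpG", A = "CpT<->TpT"))
  }
})

test_that("event counts are conserved and strand symmetry holds", {
  set.seed(71)
  for (k in 1:5) {
    ref <- randSeq(150, gc = 0.55)
    m <- ripMutate(ref, 0.2)
    aln <- pairAlign(m$seq, ref)
    ev <- classifySubstitutions(aln)
    # conservation: one event per mismatch column
    mm <- sum(strsplit(aln$q, "")[[1]] != strsplit(aln$r, "")[[1]])
    expect_equal(nrow(ev), mm)
    expect_equal(sum(ev$type == "C->T") + sum(ev$type == "G->A") +
                   sum(ev$type == "other"), nrow(ev))
    # reverse-complementing both strands maps C->T events to G->A events
    # at mirrored positions with identical context classes
    rc <- function(s) as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s)))
    ev2 <- classifySubstitutions(list(q = rc(m$seq), r = rc(ref)))
    L <- nchar(ref)
    ev2 <- ev2[order(L + 1 - ev2$position), ]
    expect_equal(L + 1 - ev2$position, ev$position)
    expect_equal(ifelse(ev$type == "C->T", "G->A",
                        ifelse(ev$type == "G->A", "C->T", "other")),
                 ev2$type)
    expect_equal(ev$context_class, ev2$context_class)
  }
})

test_that("mutation spectra report counts and two frequency denominators", {
  # 10 C->T + 5 G->A + 1 A->G over 400 comparable sites
  set.seed(81)
  ch <- strsplit(randSeq(400, gc = 0.5), "")[[1]]
  cpos <- sample(which(ch == "C"), 10)
  gpos <- sample(which(ch == "G"), 5)
  apos <- sample(which(ch == "A"), 1)
  qch <- ch
  qch[cpos] <- "T"; qch[gpos] <- "A"; qch[apos] <- "G"
  aln <- list(q = paste(qch, collapse = ""), r = paste(ch, collapse = ""))
  spec <- mutationSpectrum(classifySubstitutions(aln),
                           alignmentSiteCounts(aln))
  tot <- spec[spec$region == "total", ]
  expect_equal(tot$n_CtoT, 10)
  expect_equal(tot$n_GtoA, 5)
  expect_equal(tot$n_other, 1)
  expect_equal(tot$comparable, 400)
  expect_equal(tot$f_CtoT, 0.025)
  expect_equal(tot$f_GtoA, 0.0125)
  expect_equal(tot$f_other, 0.0025)
  expect_equal(tot$f_CtoT_perC, 10 / sum(ch == "C"))
  expect_equal(tot$f_GtoA_perG, 5 / sum(ch == "G"))

  empty <- mutationSpectrum(classifySubstitutions(list(q = "ACGT",
                                                       r = "ACGT")),
                            alignmentSiteCounts(list(q = "ACGT",
                                                     r = "ACGT")))
  expect_true(all(empty[empty$region == "total",
                        c("n_CtoT", "n_GtoA", "n_other")] == 0))
  expect_equal(attr(empty, "dominant_class"), "none")
})

test_that("recovered transition frequency matches the simulator ground truth", {
  set.seed(91)
  ref <- randomAncestor()
  m <- ripMutate(ref, 0.15)
  cmp <- compareToReference(m$seq, ref)
  tot <- cmp$spectrum[cmp$spectrum$region == "total", ]
  expect_equal(tot$n_CtoT + tot$n_GtoA, nrow(m$events))
  expect_equal(tot$f_CtoT + tot$f_GtoA, nrow(m$events) / nchar(ref))
})

test_that("pseudogene calling respects both thresholds", {
  mkspec <- function(nct, nga, nother) {
    set.seed(5)
    ch <- strsplit(randSeq(300, gc = 0.6), "")[[1]]
    qch <- ch
    qch[sample(which(ch == "C"), nct)] <- "T"
    qch[sample(which(ch == "G"), nga)] <- "A"
    if (nother > 0) qch[sample(which(ch == "A"), nother)] <- "C"
    aln <- list(q = paste(qch, collapse = ""), r = paste(ch, collapse = ""))
    mutationSpectrum(classifySubstitutions(aln), alignmentSiteCounts(aln))
  }
  expect_equal(callPseudogene(mkspec(20, 5, 1))$status, "pseudogene")
  expect_equal(callPseudogene(mkspec(0, 0, 0))$status, "functional-like")
  # boundary enumeration around the defaults
  expect_equal(callPseudogene(mkspec(1, 1, 2))$status, "functional-like")
  expect_equal(callPseudogene(mkspec(1, 1, 2), minTransitions = 1,
                              dominanceRatio = 1)$status, "pseudogene")
  expect_equal(callPseudogene(mkspec(2, 1, 0))$status, "pseudogene")
  expect_equal(callPseudogene(mkspec(2, 0, 0))$status, "functional-like")
  expect_equal(callPseudogene(mkspec(3, 0, 2))$status, "functional-like")
  expect_equal(callPseudogene(mkspec(4, 0, 2))$status, "pseudogene")
})

test_that("RIPCAL comparison picks the highest-GC consensus and ranks contexts", {
  # one functional + one copy carrying only CpA-class changes
  ref <- "ATCAGCATTCAATCAGG"
  qry <- "ATTAGTATTTAATTAGG"   # every CpA -> TpA
  rc <- ripcalCompare(c(f = ref, p = qry))
  expect_equal(rc$consensus, "f")
  expect_equal(rc$ranking$context_class[1], "CpA<->TpA")
  expect_true(all(rc$tallies["p", c("CpC<->TpC", "CpG<->TpG")] == 0))

  ident <- ripcalCompare(c(a = "ACGT", b = "ACGT", c = "ACGT"))
  expect_true(all(ident$tallies == 0))

  # equal GC: deterministic tie toward the lexicographically smallest id
  tie <- ripcalCompare(c(b = "GCAT", a = "CGTA", c = "ATAT"))
  expect_equal(tie$consensus, "a")

  expect_error(ripcalCompare(c(a = "ACGT")), ">= 2")
})

test_that("the RIPCAL dominant class recovers the simulator's favoured context", {
  set.seed(131)
  anc <- randomAncestor()
  for (sev in c(0.05, 0.15, 0.3)) {
    copies <- vapply(1:12, function(i) ripMutate(anc, sev)$seq, character(1))
    names(copies) <- paste0("p", 1:12)
    rc <- ripcalCompare(c(c(anc = anc), copies))
    expect_equal(rc$consensus, "anc")
    expect_equal(rc$ranking$context_class[1], "CpA<->TpA")
  }
})

test_that("RIP indices follow the dinucleotide definitions", {
  # hand-counted oracle on a short string
  s <- "TACATGTA"  # TA:2 AT:1 CA:1 TG:1 AC:1 GT:1
  ri <- ripIndices(c(x = s))
  expect_equal(ri$tpa_apt, 2 / 1)
  expect_equal(ri$cpa_tpg_over_apc_gpt, (1 + 1) / (1 + 1))
  expect_true(is.na(ripIndices(c(y = "CCCC"))$tpa_apt))
})

test_that("dataset scan calls pseudogenes and summarizes occurrence", {
  sim <- smallSim(seed = 17, nInd = 20, occurrence = 0.5)
  x <- sim$records
  sc <- ripScan(x)
  truth <- sim$truth
  called <- sc$calls$status == "pseudogene"
  expect_true(all(sc$calls$query %in%
                    truth$id[truth$truth_status == "pseudogene"]))
  expect_true(all(called))    # severity 0.2 pseudogenes are unmistakable
  gs <- groupMutationSummary(sc, x)
  allrow <- gs$occurrence[gs$occurrence$locality == "(all)", ]
  expect_equal(allrow$n_carriers,
               length(unique(sc$calls$individual_id[called])))
  expect_equal(allrow$n_tested, 20)
  expect_equal(allrow$percent, round(100 * allrow$n_carriers / 20, 2))
  # per-region rows sum to the total transition load
  expect_equal(sum(gs$byRegion$mean_n_CtoT + gs$byRegion$mean_n_GtoA),
               gs$mutation$mean_transitions)
})

test_that("a dataset with no pseudogenes reports zero occurrence", {
  sim <- smallSim(seed = 23, nInd = 12, occurrence = 0)
  sc <- ripScan(sim$records)
  gs <- groupMutationSummary(sc, sim$records)
  expect_equal(nrow(sc$calls), 0L)
  allrow <- gs$occurrence[gs$occurrence$locality == "(all)", ]
  expect_equal(allrow$n_carriers, 0L)
  expect_equal(allrow$percent, 0)
})

test_that("reference policy controls orphan queries", {
  seqs <- c(i1_f = "ACGTACGTCC", i1_p = "ATGTATGTCC",
            i2_p = "ATGTATGTTT")
  md <- data.frame(id = names(seqs),
                   individual_id = sub("_.*", "", names(seqs)),
                   status = c("functional", "candidate", "candidate"),
                   stringsAsFactors = FALSE)
  x <- itsSequenceSet(seqs, md)
  expect_error(ripScan(x, scope = "full",
                       referencePolicy = "same-individual"), "i2")
  sc <- ripScan(x, scope = "full")   # auto falls back to the consensus
  expect_equal(sort(sc$calls$query), c("i1_p", "i2_p"))
  expect_equal(sc$calls$reference[sc$calls$query == "i2_p"], "i1_f")
})
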