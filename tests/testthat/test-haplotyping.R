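test_that("identical sequences collapse into deterministic haplotype classes", {
  x <- itsSequenceSet(c(s1 = "ACGT", s2 = "ACGT", s3 = "ACGT", s4 = "AAGT"))
  ht <- collapseHaplotypes(x)
  expect_equal(nHaplotypes(ht), 2L)
  expect_equal(sort(haplotypeClasses(ht)$size), c(1L, 3L))
  expect_equal(haplotypeClasses(ht)$haplotype_id, c("h1", "h2"))
  expect_equal(haplotypeClasses(ht)$representative, c("s1", "s4"))
  expect_equal(unname(classMap(ht)[c("s1", "s4")]), c("h1", "h2"))
})

test_that("normalization folds case and shared gap columns, ambiguities literal", {
  x <- itsSequenceSet(c(a = "ACGT", b = "ACGT"))
  # case handled at ingest; exercise the switch directly on the raw strings
  expect_equal(nHaplotypes(collapseHaplotypes(x)), 1L)

  g <- itsSequenceSet(c(a = "AC-GT", b = "AC-GT", c = "ACC-T"))
  expect_equal(nHaplotypes(collapseHaplotypes(g)), 2L)

  amb <- itsSequenceSet(c(a = "ACNT", b = "ACAT"))
  expect_equal(nHaplotypes(collapseHaplotypes(amb)), 2L)  # N != A

  uneq <- itsSequenceSet(c(a = "ACGT", b = "ACGTT"))
  expect_error(collapseHaplotypes(uneq), "align")
  expect_equal(nHaplotypes(collapseHaplotypes(uneq, region = c(1, 4))), 1L)
})

test_that("collapsing matches the all-pairs identity oracle on planted haplotypes", {
  set.seed(101)
  planted <- replicate(7, randSeq(80))
  for (n in c(40, 100)) {
    pick <- sample.int(7, n, replace = TRUE)
    # guarantee every planted haplotype appears
    pick[1:7] <- 1:7
    seqs <- setNames(planted[pick], paste0("q", seq_len(n)))
    ht <- collapseHaplotypes(itsSequenceSet(seqs))
    oracle <- bruteHaplotypePartition(as.list(seqs))
    expect_equal(nHaplotypes(ht), length(unique(oracle)))
    # same partition: class labels must be a bijection of oracle labels
    got <- classMap(ht)[paste0("q", seq_len(n))]
    expect_equal(length(unique(paste(got, oracle))),
                 length(unique(oracle)))
    # partition property / count conservation
    expect_equal(sum(haplotypeClasses(ht)$size), n)
    expect_setequal(unlist(strsplit(haplotypeClasses(ht)$members, ";")),
                    names(seqs))
  }
})

test_that("haplotype partition is invariant under input order permutation", {
  set.seed(55)
  planted <- replicate(4, randSeq(60))
  seqs <- setNames(planted[sample.int(4, 30, replace = TRUE)],
                   paste0("s", 1:30))
  ht1 <- collapseHaplotypes(itsSequenceSet(seqs))
  perm <- sample(30)
  ht2 <- collapseHaplotypes(itsSequenceSet(seqs[perm]))
  expect_equal(nHaplotypes(ht1), nHaplotypes(ht2))
  m1 <- classMap(ht1); m2 <- classMap(ht2)[names(m1)]
  # same grouping even if ids differ
  expect_equal(length(unique(paste(m1, m2))), nHaplotypes(ht1))
})

test_that("per-individual haplotype counts cover the 1..8 range", {
  clones <- itsSequenceSet(
    setNames(rep("ACGTACGT", 3), paste0("i1_c", 1:3)),
    data.frame(id = paste0("i1_c", 1:3), individual_id = "i1",
               stringsAsFactors = FALSE))
  ht <- collapseHaplotypes(clones)
  tab <- haplotypesPerIndividual(ht, clones)
  expect_equal(tab$n_haplotypes, 1L)

  set.seed(9)
  eight <- setNames(replicate(8, randSeq(40)), paste0("i2_c", 1:8))
  x8 <- itsSequenceSet(eight, data.frame(id = names(eight),
                                         individual_id = "i2",
                                         stringsAsFactors = FALSE))
  tab8 <- haplotypesPerIndividual(collapseHaplotypes(x8), x8)
  expect_equal(tab8$n_haplotypes, 8L)

  emptyHt <- collapseHaplotypes(clones)
  empty <- haplotypesPerIndividual(
    new("HaplotypeTable",
        classes = data.frame(haplotype_id = character(), size = integer(),
                             representative = character(),
                             members = character()),
        classMap = setNames(character(), character()), nSequences = 0L),
    clones)
  expect_equal(nrow(empty), 0L)
})

test_that("haplotype sharing distinguishes the three population patterns", {
  # i1,i2: same functional, same pseudogene       -> (same, shared)
  # i1,i3: same functional, disjoint pseudogenes  -> (same, not shared)
  # i1,i4: different functional, shared pseudogene-> (different, shared)
  seqs <- c(i1_f = "ACGTACGT", i2_f = "ACGTACGT", i3_f = "ACGTACGT",
            i4_f = "ACGAACGT",
            i1_p = "ATGTATGT", i2_p = "ATGTATGT", i3_p = "ACATACAT",
            i4_p = "ATGTATGT")
  md <- data.frame(id = names(seqs),
                   individual_id = sub("_.*", "", names(seqs)),
                   status = rep(c("functional", "pseudogene"), each = 4),
                   stringsAsFactors = FALSE)
  x <- itsSequenceSet(seqs, md)
  st <- seqStatus(x)
  htF <- collapseHaplotypes(x[names(st)[st == "functional"]])
  htP <- collapseHaplotypes(x[names(st)[st == "pseudogene"]])
  sh <- haplotypeSharing(htF, htP, x)
  row <- function(a, b)
    sh$pairs[sh$pairs$ind_a == a & sh$pairs$ind_b == b, ]
  expect_true(row("i1", "i2")$same_functional)
  expect_true(row("i1", "i2")$shared_pseudogene)
  expect_true(row("i1", "i3")$same_functional)
  expect_false(row("i1", "i3")$shared_pseudogene)
  expect_false(row("i1", "i4")$same_functional)
  expect_true(row("i1", "i4")$shared_pseudogene)
  expect_equal(sum(sh$summary$n_pairs), nrow(sh$pairs))
})
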