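# Brute-force oracle: clade test by enumerating the tip set below every
# edge with an independent edge-walk (no ape machinery).
bruteMonophyly <- function(tree, tips, outgroup) {
  labs <- tree$tip.label
  target <- sort(match(tips, labs))
  if (length(target) <= 1) return(TRUE)
  ntip <- length(labs)
  below <- function(node) {
    if (node <= ntip) return(node)
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    sort(unlist(lapply(kids, below)))
  }
  for (e in seq_len(nrow(tree$edge))) {
    s <- below(tree$edge[e, 2])
    if (identical(sort(s), target) ||
        identical(sort(setdiff(seq_len(ntip), s)), target))
      return(TRUE)
  }
  FALSE
}

test_that("three-taxon NJ solves the three-point equations exactly", {
  d <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- njTree(d)
  co <- ape::cophenetic.phylo(tr)
  expect_equal(co[rownames(d), colnames(d)], d, tolerance = 1e-12)
  # closed form: a = (dAB + dAC - dBC)/2 = 2, b = 3, c = 7
  edge_len <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(edge_len[c("A", "B", "C")]), c(2, 3, 7))
})

test_that("additive matrices from known trees are recovered exactly", {
  # fixed 4-taxon additive case
  tree4 <- ape::read.tree(text = "((A:2,B:3):1,C:4,D:5);")
  d4 <- ape::cophenetic.phylo(tree4)
  tr <- njTree(d4[LETTERS[1:4], LETTERS[1:4]])
  expect_equal(ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]],
               d4[LETTERS[1:4], LETTERS[1:4]], tolerance = 1e-9)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tree4), tr)), 0)

  # random additive matrices, 5..8 taxa
  set.seed(42)
  for (n in 5:8) {
    rt <- ape::rtree(n, rooted = FALSE)
    rt$edge.length <- rt$edge.length + 0.5   # keep branches well positive
    dd <- ape::cophenetic.phylo(rt)
    tr <- njTree(dd)
    expect_equal(ape::cophenetic.phylo(tr)[rownames(dd), colnames(dd)], dd,
                 tolerance = 1e-9)
    expect_equal(as.numeric(ape::dist.topo(rt, tr)), 0)
  }
})

test_that("NJ matches the reference implementation on noisy matrices", {
  set.seed(43)
  for (k in 1:4) {
    n <- sample(5:9, 1)
    p <- matrix(runif(n * n, 0.05, 0.4), n)
    d <- (p + t(p)) / 2; diag(d) <- 0
    rownames(d) <- colnames(d) <- paste0("t", 1:n)
    mine <- njTree(d)
    ref <- ape::nj(as.dist(d))
    expect_equal(as.numeric(ape::dist.topo(mine, ref)), 0)
  }
})

test_that("equal distances resolve through the smallest-index tie rule", {
  d <- matrix(1, 4, 4); diag(d) <- 0
  rownames(d) <- colnames(d) <- c("w", "x", "y", "z")
  tr1 <- njTree(d)
  tr2 <- njTree(d)
  expect_identical(ape::write.tree(tr1), ape::write.tree(tr2))
  # the first join must pair the first two taxa
  expect_true(bruteMonophyly(tr1, c("w", "x"), "z"))
})

test_that("undefined or asymmetric distances are rejected with names", {
  d <- matrix(c(0, NA, NA, 0), 2, 2)
  expect_error(njTree(d), "at least 3")
  d3 <- matrix(c(0, 1, NA, 1, 0, 1, NA, 1, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  expect_error(njTree(d3), "a-c")
})

test_that("negative branch estimates are clamped and flagged", {
  d <- matrix(c(0, 0.1, 0.15, 0.2,
                0.1, 0, 0.05, 0.25,
                0.15, 0.05, 0, 0.03,
                0.2, 0.25, 0.03, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- njTree(d)
  expect_true(all(tr$edge.length >= 0))
  expect_true(attr(tr, "clampedBranches") >= 0)
})

test_that("monophyly testing agrees with brute-force bipartition enumeration", {
  cat4 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_true(isMonophyletic(cat4, c("A", "B"), "D"))
  expect_false(isMonophyletic(cat4, c("A", "C"), "D"))
  expect_true(isMonophyletic(cat4, c("A", "B", "C"), "D"))
  expect_error(isMonophyletic(cat4, c("A", "Q"), "D"), "Q")
  expect_error(isMonophyletic(cat4, c("A", "B"), character(0)), "outgroup")
  expect_error(isMonophyletic(cat4, c("A", "D"), "D"), "disjoint")

  set.seed(44)
  for (k in 1:10) {
    tr <- ape::rtree(12)
    labs <- tr$tip.label
    out <- sample(labs, 1)
    grp <- sample(setdiff(labs, out), sample(2:6, 1))
    expect_equal(isMonophyletic(tr, grp, out),
                 bruteMonophyly(tr, grp, out))
  }
  # and on clades that are genuinely monophyletic by construction
  for (k in 1:10) {
    tr <- ape::rtree(10)
    node <- sample((12):(10 + tr$Nnode), 1)
    grp <- ape::extract.clade(tr, node)$tip.label
    out <- setdiff(tr$tip.label, grp)[1]
    if (length(grp) >= 2 && !is.na(out)) {
      expect_true(isMonophyletic(tr, grp, out))
      expect_true(bruteMonophyly(tr, grp, out))
    }
  }
})

test_that("bootstrap support is 1 for the trivial group and NA without signal", {
  set.seed(45)
  seqs <- c(a = randSeq(120), out = randSeq(120))
  seqs["b"] <- local({
    ch <- strsplit(seqs[["a"]], "")[[1]]
    i <- sample(120, 3); ch[i] <- "T"; paste(ch, collapse = "")
  })
  seqs["c"] <- seqs[["b"]]
  bs <- bootstrapSupport(seqs, group = c("a", "b", "c"), outgroup = "out",
                         nReps = 20, seed = 1)
  expect_equal(as.numeric(bs), 1.0)

  flat <- c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT")
  expect_true(is.na(bootstrapSupport(flat, c("a", "b"), "c", nReps = 5,
                                     seed = 1)))
})

test_that("well-separated clusters get high bootstrap support", {
  set.seed(46)
  base <- randSeq(300, gc = 0.55)
  clusterA <- c(a1 = base, a2 = base, a3 = base)
  mutated <- ripMutate(base, 0.25)$seq
  clusterB <- c(b1 = mutated, b2 = mutated, b3 = mutated)
  og <- local({
    ch <- strsplit(base, "")[[1]]
    i <- sample(300, 35)
    for (p in i) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    paste(ch, collapse = "")
  })
  aln <- c(clusterA, clusterB, out = og)
  bs <- bootstrapSupport(aln, group = names(clusterB), outgroup = "out",
                         nReps = 100, seed = 2)
  expect_gte(as.numeric(bs), 0.95)
})
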