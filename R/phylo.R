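#' Neighbor-joining tree with a fixed tie-breaking contract
#'
#' Standard agglomerative neighbor joining: at each step the pair (i, j)
#' minimizing the Q-criterion `(n-2) d(i,j) - R(i) - R(j)` is joined, with
#' ties broken deterministically toward the smallest (i, j) index pair in
#' the current node order (original input order, then creation order of
#' internal nodes). Branch lengths come from the standard two-point
#' formulas; the final three nodes are resolved by the three-point
#' equations. Negative branch-length estimates are clamped to zero and
#' counted in the `clampedBranches` attribute of the result.
#'
#' @param d A `pDistanceMatrix` (from [pDistanceMatrix()]), a symmetric
#'   numeric matrix with dimnames, or a [stats::dist].
#' @return An unrooted [ape::phylo] tree whose tip labels are the matrix
#'   ids, with attribute `clampedBranches`.
#' @export
njTree <- function(d) {
  if (inherits(d, "pDistanceMatrix")) d <- d$d
  if (inherits(d, "dist")) d <- as.matrix(d)
  n <- nrow(d)
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", 1:n)
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  if (any(is.na(d) | !is.finite(d))) {
    bad <- which(is.na(d) | !is.finite(d), arr.ind = TRUE)
    bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
    stop("undefined distances for pair(s): ",
         paste(paste0(rownames(d)[bad[, 1]], "-", colnames(d)[bad[, 2]]),
               collapse = ", "))
  }
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix is not symmetric")
  clamped <- 0L
  bl <- function(x) {
    if (x < 0) { clamped <<- clamped + 1L; 0 } else x
  }
  lab <- rownames(d)
  node <- ifelse(grepl("[ ():,;']", lab), paste0("'", lab, "'"), lab)
  D <- d
  while (length(node) > 3) {
    m <- length(node)
    R <- rowSums(D)
    Q <- (m - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    hit <- which(Q == min(Q), arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- hit[1, 1]; j <- hit[1, 2]
    li <- bl(D[i, j] / 2 + (R[i] - R[j]) / (2 * (m - 2)))
    lj <- bl(D[i, j] - (D[i, j] / 2 + (R[i] - R[j]) / (2 * (m - 2))))
    merged <- sprintf("(%s:%.15g,%s:%.15g)", node[i], li, node[j], lj)
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    node <- c(node[keep], merged)
    D <- D2
  }
  la <- bl((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  lb <- bl((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  lc <- bl((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);",
                 node[1], la, node[2], lb, node[3], lc)
  tree <- ape::read.tree(text = nwk)
  attr(tree, "clampedBranches") <- clamped
  tree
}

#' Test monophyly of a tip set after rooting on an outgroup
#'
#' True iff, once the tree is rooted on the outgroup edge, the given tips
#' form a clade — equivalently, iff some edge of the unrooted tree
#' bipartitions the tips exactly against everything else (the outgroup
#' included). Singleton tip sets are trivially monophyletic.
#'
#' @param tree An [ape::phylo] tree.
#' @param tips Character ids of the group to test.
#' @param outgroup Character ids defining the rooting; must be non-empty
#'   and disjoint from `tips`.
#' @return Logical.
#' @export
isMonophyletic <- function(tree, tips, outgroup) {
  labs <- tree$tip.label
  unknown <- setdiff(c(tips, outgroup), labs)
  if (length(unknown))
    stop("unknown tip id(s): ", paste(unknown, collapse = ", "))
  if (!length(outgroup)) stop("outgroup must be non-empty")
  if (length(intersect(tips, outgroup)))
    stop("tips and outgroup must be disjoint")
  tips <- unique(tips)
  if (length(tips) <= 1) return(TRUE)
  target <- sort(match(tips, labs))
  parts <- ape::prop.part(tree)
  all_tips <- seq_along(labs)
  for (p in parts) {
    s <- sort(p)
    if (identical(s, target) ||
        identical(sort(setdiff(all_tips, s)), target))
      return(TRUE)
  }
  # pendant bipartitions: complement of a single tip
  for (k in all_tips) {
    if (identical(sort(setdiff(all_tips, k)), target)) return(TRUE)
  }
  FALSE
}

#' Bootstrap support for the monophyly of a group under NJ
#'
#' Resamples alignment columns with replacement, rebuilds the p-distance
#' matrix and NJ tree for each replicate, and reports the fraction of
#' replicates in which the group is monophyletic relative to the outgroup.
#' An alignment with no variable comparable column has no resampling
#' signal: the support is returned as `NA` (flagged). Replicates in which
#' a resampled pair has no comparable site are dropped and counted in the
#' `n_dropped` attribute.
#'
#' @param x An aligned [ItsSequenceSet], `DNAStringSet` or named character
#'   vector.
#' @param group,outgroup Tip id sets (see [isMonophyletic()]).
#' @param nReps Number of bootstrap replicates (default 100).
#' @param seed Integer seed.
#' @return Support fraction in `[0, 1]` (or `NA`), with attributes
#'   `n_valid` and `n_dropped`.
#' @export
bootstrapSupport <- function(x, group, outgroup, nReps = 100, seed) {
  stopifnot(nReps >= 1)
  if (!missing(seed)) set.seed(seed)
  s <- .asSeqChar(x)
  if (length(unique(nchar(s))) != 1) stop("sequences must be aligned")
  M <- do.call(rbind, strsplit(s, "", fixed = TRUE))
  rownames(M) <- names(s)
  ok <- .isACGT(M)
  varying <- vapply(seq_len(ncol(M)), function(j) {
    v <- M[ok[, j], j]
    length(unique(v)) > 1
  }, logical(1))
  if (!any(varying))
    return(structure(NA_real_, n_valid = 0L, n_dropped = 0L,
                     reason = "no variable comparable columns"))
  hits <- 0L; valid <- 0L; dropped <- 0L
  for (r in seq_len(nReps)) {
    cols <- sample.int(ncol(M), ncol(M), replace = TRUE)
    rs <- apply(M[, cols, drop = FALSE], 1, paste, collapse = "")
    pm <- tryCatch(pDistanceMatrix(rs), error = function(e) NULL)
    if (is.null(pm) || any(is.na(pm$d))) { dropped <- dropped + 1L; next }
    tr <- njTree(pm)
    valid <- valid + 1L
    if (isMonophyletic(tr, group, outgroup)) hits <- hits + 1L
  }
  if (valid == 0L)
    return(structure(NA_real_, n_valid = 0L, n_dropped = dropped))
  structure(hits / valid, n_valid = valid, n_dropped = dropped)
}

#' Write a tree to Newick
#'
#' Branch lengths are written to 6 significant digits; labels containing
#' whitespace are quoted.
#'
#' @param tree An [ape::phylo].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
writeNewick <- function(tree, path) {
  tree$tip.label <- ifelse(grepl("\\s", tree$tip.label),
                           paste0("'", tree$tip.label, "'"),
                           tree$tip.label)
  ape::write.tree(tree, file = path, digits = 6)
  invisible(path)
}
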