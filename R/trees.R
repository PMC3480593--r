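#' Neighbor-joining tree from a distance matrix
#'
#' Implements the Saitou-Nei agglomeration with the Studier-Keppler
#' Q-criterion and the standard branch-length formulas. When several pairs
#' tie on the minimum of Q, the pair whose (sorted) cluster labels are
#' lexicographically smallest is joined, where a cluster is labelled by the
#' smallest leaf label it contains; this makes the reconstruction
#' deterministic and invariant to the input order of taxa. Negative branch
#' lengths are retained (they do not affect topology); their count is
#' attached as attribute `"negative_branches"`.
#'
#' @param D symmetric numeric matrix with zero diagonal and taxon
#'   dimnames, or a [PooledDistance-class].
#' @return an unrooted `ape::phylo` tree.
#' @export
neighborJoining <- function(D) {
  if (is(D, "PooledDistance")) D <- D@D
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  if (is.null(rownames(D))) stop("distance matrix must carry taxon labels")
  if (!all(is.finite(D))) stop("non-finite distance entry")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  d <- D
  labels <- rownames(D)        # cluster tie-break label: smallest leaf label
  nwk <- rownames(D)           # growing Newick fragment per cluster
  nneg <- 0L
  fmt <- function(x) sprintf("%.10g", x)
  while (nrow(d) > 3L) {
    r <- nrow(d)
    u <- rowSums(d)
    Q <- (r - 2) * d - outer(u, u, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # lexicographically smallest sorted label pair
    lab1 <- pmin(labels[cand[, 1]], labels[cand[, 2]])
    lab2 <- pmax(labels[cand[, 1]], labels[cand[, 2]])
    best <- order(lab1, lab2)[1]
    i <- cand[best, 1]; j <- cand[best, 2]
    bi <- d[i, j] / 2 + (u[i] - u[j]) / (2 * (r - 2))
    bj <- d[i, j] - bi
    nneg <- nneg + sum(c(bi, bj) < 0)
    newNwk <- paste0("(", nwk[i], ":", fmt(bi), ",", nwk[j], ":", fmt(bj), ")")
    newLab <- min(labels[i], labels[j])
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    labels <- c(labels[keep], newLab)
    nwk <- c(nwk[keep], newNwk)
  }
  # final three clusters around the central node
  b1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  b3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nneg <- nneg + sum(c(b1, b2, b3) < 0)
  txt <- paste0("(", nwk[1], ":", fmt(b1), ",", nwk[2], ":", fmt(b2),
                ",", nwk[3], ":", fmt(b3), ");")
  tr <- ape::read.tree(text = txt)
  attr(tr, "negative_branches") <- nneg
  tr
}

#' Parse / write Newick
#'
#' Thin validated wrappers around `ape::read.tree()` / `ape::write.tree()`.
#' Parsing rejects malformed strings and duplicate leaf labels; writing
#' keeps 10 significant digits so a round trip preserves topology, labels
#' and branch lengths.
#'
#' @param text a Newick string.
#' @param tree an `ape::phylo` tree.
#' @param path optional output file for [writeNewick()]; if `NULL` the
#'   Newick string is returned.
#' @return [parseNewick()]: an `ape::phylo`; [writeNewick()]: the Newick
#'   string (invisibly if written to `path`).
#' @export
parseNewick <- function(text) {
  tr <- tryCatch(ape::read.tree(text = text), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("malformed Newick string")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf label: ",
         tr$tip.label[duplicated(tr$tip.label)][1])
  tr
}

#' @rdname parseNewick
#' @export
writeNewick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree, digits = 10)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Partition (topological) distance between two trees
#'
#' The number of non-trivial bipartitions present in exactly one of the
#' two unrooted trees (the Robinson-Foulds symmetric difference); zero iff
#' the unrooted topologies agree, at most `2(n-3)` for binary trees.
#'
#' @param t1,t2 `ape::phylo` trees over the same leaf set.
#' @return integer partition distance.
#' @export
partitionDistance <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets")
  as.integer(suppressMessages(
    phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2),
                      check.labels = TRUE)))
}

## All splits of the unrooted tree, each as the sorted side containing the
## alphabetically first leaf (canonical form), including trivial splits.
.canonicalSplits <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- tree$tip.label
  anchor <- sort(tips)[1]
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  canon <- function(s) {
    side <- labs[s]
    if (!(anchor %in% side)) side <- setdiff(tips, side)
    paste(sort(side), collapse = "\r")
  }
  out <- unique(c(vapply(parts, canon, character(1)),
                  vapply(seq_along(tips), function(i) canon(i), character(1))))
  out
}

#' Does a tree contain a given cluster?
#'
#' TRUE iff the bipartition (subset | remaining taxa) exists in the
#' unrooted tree. Trivial splits (single taxon, or all but one) are always
#' present. For a 2-taxon subset on 4 taxa this is the cherry test used
#' for clade-support counting.
#'
#' @param tree an `ape::phylo`.
#' @param taxa nonempty proper subset of the tree's leaf labels.
#' @return logical.
#' @export
hasCluster <- function(tree, taxa) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  unknown <- setdiff(taxa, tips)
  if (length(unknown)) stop("unknown taxon: ", unknown[1])
  if (length(taxa) == 0L || length(taxa) >= length(tips))
    stop("query must be a nonempty proper subset of the taxa")
  if (length(taxa) == 1L || length(taxa) == length(tips) - 1L) return(TRUE)
  anchor <- sort(tips)[1]
  side <- if (anchor %in% taxa) taxa else setdiff(tips, taxa)
  key <- paste(sort(side), collapse = "\r")
  key %in% .canonicalSplits(tree)
}

#' Longest tip-to-tip path length of a tree
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @return maximum pairwise patristic distance.
#' @export
maxPairwisePath <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  max(ape::cophenetic.phylo(tree))
}
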