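# Fixture builders and independent oracles used across the suite.

makeAln <- function(seqs, name = "locus", alphabet = "AA") {
  locusAlignment(seqs, name = name, alphabet = alphabet)
}

# Minimal GeneDistanceSet with prescribed per-locus k/V matrices.
makeGds <- function(kList, vList, L, taxa, model = "poisson") {
  for (h in names(kList)) {
    dimnames(kList[[h]]) <- list(taxa, taxa)
    dimnames(vList[[h]]) <- list(taxa, taxa)
  }
  new("GeneDistanceSet", k = kList, V = vList,
      L = setNames(as.numeric(L), names(kList)),
      taxa = taxa, model = model, saturated = FALSE)
}

# Symmetric matrix where every unordered pair of `taxa` gets value `x`
# (scalar or per-pair vector in combn order).
pairMatrix <- function(taxa, x) {
  n <- length(taxa)
  m <- matrix(0, n, n, dimnames = list(taxa, taxa))
  pr <- combn(n, 2)
  m[t(pr)] <- x
  m[t(pr[2:1, , drop = FALSE])] <- x
  m
}

# Random binary unrooted tree with positive branch lengths and its
# additive distance matrix.
randomAdditiveCase <- function(ntaxa) {
  tr <- ape::rtree(ntaxa, rooted = FALSE,
                   br = function(n) runif(n, 0.05, 1))
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}

# --- independent split oracles (recursive descent over the edge matrix,
# no calls into the package's tree code or phangorn) ---

tipsBelow <- function(tree, node, ntip) {
  if (node <= ntip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, tipsBelow, tree = tree, ntip = ntip))
}

# Non-trivial splits of an unrooted tree, canonicalized to the side
# holding the alphabetically first tip.
bruteSplits <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  anchor <- sort(tree$tip.label)[1]
  keys <- character()
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    if (child <= ntip) next
    side <- tipsBelow(tree, child, ntip)
    if (length(side) <= 1 || length(side) >= ntip - 1) next
    if (!(anchor %in% side)) side <- setdiff(tree$tip.label, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

bruteRF <- function(t1, t2) {
  s1 <- bruteSplits(t1); s2 <- bruteSplits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# Dense random search over the weight simplex (the optimality oracle).
simplexGrid <- function(nGenes, nPoints, seed = 42) {
  set.seed(seed)
  w <- matrix(rexp(nPoints * nGenes), nPoints, nGenes)
  w / rowSums(w)
}
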