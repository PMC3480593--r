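#' @import methods
#' @importFrom stats rgamma rpois runif rlnorm var setNames weights qnorm
#' @importFrom utils combn head
NULL

.ALPHABETS <- c("AA", "DNA")

#' Residues considered informative for each alphabet
#'
#' Gap and ambiguity characters (anything outside the alphabet proper) are
#' removed by [completeDeletion()] before distances are computed.
#' @keywords internal
.alphabetChars <- function(alphabet) {
  switch(alphabet,
    AA  = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
    DNA = c("A", "C", "G", "T"),
    stop("unknown alphabet: ", alphabet)
  )
}

#' LocusAlignment: one aligned locus
#'
#' Container for a single gene's multiple sequence alignment. Sequences are
#' stored as a character matrix with one row per taxon and one column per
#' alignment site, so column operations (complete deletion, site bootstrap)
#' are cheap.
#'
#' @slot name single gene label.
#' @slot alphabet `"AA"` or `"DNA"`.
#' @slot seqs character matrix, rows named by taxon, one residue per cell,
#'   uppercase.
#'
#' @seealso [readLocusFasta()], [completeDeletion()]
#' @exportClass LocusAlignment
setClass("LocusAlignment",
  representation(name = "character", alphabet = "character",
                 seqs = "matrix"))

setValidity("LocusAlignment", function(object) {
  msg <- character()
  if (length(object@name) != 1L || is.na(object@name))
    msg <- c(msg, "'name' must be a single non-NA string")
  if (length(object@alphabet) != 1L || !object@alphabet %in% .ALPHABETS)
    msg <- c(msg, "'alphabet' must be one of \"AA\", \"DNA\"")
  if (!is.character(object@seqs))
    msg <- c(msg, "'seqs' must be a character matrix")
  tx <- rownames(object@seqs)
  if (is.null(tx) || anyDuplicated(tx))
    msg <- c(msg, "taxon labels must be present and unique")
  if (nrow(object@seqs) >= 1L && ncol(object@seqs) >= 1L &&
      any(object@seqs != toupper(object@seqs)))
    msg <- c(msg, "sequences must be stored uppercase")
  if (length(msg)) msg else TRUE
})

#' MultiLocusDataset: a set of loci over a shared taxon set
#'
#' @slot loci named list of [LocusAlignment-class] objects, all holding the
#'   same taxa in the same order.
#' @slot taxa shared ordered taxon labels.
#' @exportClass MultiLocusDataset
setClass("MultiLocusDataset",
  representation(loci = "list", taxa = "character"))

setValidity("MultiLocusDataset", function(object) {
  msg <- character()
  if (length(object@loci) < 1L)
    msg <- c(msg, "at least one locus is required")
  if (length(object@taxa) < 3L)
    msg <- c(msg, "at least three taxa are required")
  if (anyDuplicated(object@taxa))
    msg <- c(msg, "taxa must be unique")
  ok <- vapply(object@loci, function(l)
    is(l, "LocusAlignment") && identical(rownames(l@seqs), object@taxa),
    logical(1))
  if (!all(ok))
    msg <- c(msg, "every locus must be a LocusAlignment over the shared taxa")
  nm <- vapply(object@loci, function(l) l@name, character(1))
  if (!identical(unname(nm), names(object@loci)) || anyDuplicated(nm))
    msg <- c(msg, "locus list must be named by unique locus names")
  if (length(msg)) msg else TRUE
})

#' GeneDistanceSet: per-locus distances with sampling variances
#'
#' For every locus h and unordered taxon pair (i, j), holds the estimated
#' number of substitutions per site k(h, i, j), its delta-method sampling
#' variance V[k(h, i, j)], and the number of compared sites L(h). All
#' matrices share one taxon ordering.
#'
#' @slot k named list of symmetric distance matrices (zero diagonal).
#' @slot V named list of symmetric variance matrices (zero diagonal).
#' @slot L named numeric vector of post-deletion locus lengths.
#' @slot taxa taxon ordering common to all matrices.
#' @slot model `"poisson"` or `"k2p"`.
#' @slot saturated logical: TRUE if any pairwise distance hit the saturation
#'   guard (log argument clamped, see [poissonDistance()]).
#' @exportClass GeneDistanceSet
setClass("GeneDistanceSet",
  representation(k = "list", V = "list", L = "numeric", taxa = "character",
                 model = "character", saturated = "logical"))

setValidity("GeneDistanceSet", function(object) {
  msg <- character()
  if (!identical(names(object@k), names(object@V)) ||
      !identical(names(object@k), names(object@L)))
    msg <- c(msg, "'k', 'V' and 'L' must be named consistently by locus")
  n <- length(object@taxa)
  for (h in names(object@k)) {
    K <- object@k[[h]]; V <- object@V[[h]]
    if (!all(dim(K) == n) || !all(dim(V) == n)) {
      msg <- c(msg, sprintf("matrices for locus '%s' have wrong dimension", h))
      next
    }
    if (any(abs(K - t(K)) > 1e-12) || any(abs(V - t(V)) > 1e-12))
      msg <- c(msg, sprintf("matrices for locus '%s' are not symmetric", h))
    if (any(diag(K) != 0) || any(diag(V) != 0))
      msg <- c(msg, sprintf("matrices for locus '%s' have nonzero diagonal", h))
    if (any(V < 0, na.rm = TRUE))
      msg <- c(msg, sprintf("negative variance in locus '%s'", h))
  }
  if (length(msg)) msg else TRUE
})

#' WeightScheme: pooling weights for one of the four methods
#'
#' Per-gene methods (`noweight`, `mtt`, `mls`) store one weight per locus;
#' the per-pair least-squares method (`ls`) stores, for every unordered
#' taxon pair, one weight per locus. Weights are normalized so that, for
#' each pair, they sum to one across loci.
#'
#' @slot method one of `"noweight"`, `"ls"`, `"mtt"`, `"mls"`.
#' @slot granularity `"per_gene"` or `"per_gene_pair"`.
#' @slot weights for `per_gene`: named numeric vector over loci; for
#'   `per_gene_pair`: a loci-by-pair matrix whose columns are named
#'   `"i|j"` over unordered pairs and sum to one.
#' @slot taxa taxon ordering the pair labels refer to.
#' @exportClass WeightScheme
setClass("WeightScheme",
  representation(method = "character", granularity = "character",
                 weights = "ANY", taxa = "character"))

setValidity("WeightScheme", function(object) {
  msg <- character()
  if (!object@method %in% c("noweight", "ls", "mtt", "mls"))
    msg <- c(msg, "unknown method")
  if (!object@granularity %in% c("per_gene", "per_gene_pair"))
    msg <- c(msg, "unknown granularity")
  w <- object@weights
  if (object@granularity == "per_gene") {
    if (!is.numeric(w) || is.null(names(w)))
      msg <- c(msg, "per-gene weights must be a named numeric vector")
    else {
      if (any(w < 0)) msg <- c(msg, "weights must be nonnegative")
      if (abs(sum(w) - 1) > 1e-8)
        msg <- c(msg, "per-gene weights must sum to 1")
    }
  } else {
    if (!is.matrix(w) || is.null(rownames(w)) || is.null(colnames(w)))
      msg <- c(msg, "per-pair weights must be a loci x pair matrix")
    else {
      if (any(w < 0)) msg <- c(msg, "weights must be nonnegative")
      if (any(abs(colSums(w) - 1) > 1e-8))
        msg <- c(msg, "weights must sum to 1 within every pair")
    }
  }
  if (length(msg)) msg else TRUE
})

#' PooledDistance: the weighted multi-locus distance matrix
#'
#' @slot D symmetric pooled distance matrix over the taxa.
#' @slot scheme the [WeightScheme-class] that produced it (provenance).
#' @exportClass PooledDistance
setClass("PooledDistance",
  representation(D = "matrix", scheme = "WeightScheme"))

setValidity("PooledDistance", function(object) {
  msg <- character()
  D <- object@D
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-10)))
    msg <- c(msg, "'D' must be symmetric")
  if (any(diag(D) != 0))
    msg <- c(msg, "'D' must have a zero diagonal")
  if (is.null(rownames(D)))
    msg <- c(msg, "'D' must carry taxon labels")
  if (length(msg)) msg else TRUE
})
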