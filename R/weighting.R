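## Unordered taxon pairs in a fixed order, labelled "i|j".
.pairIndex <- function(taxa) {
  pr <- combn(length(taxa), 2L)
  list(idx = pr, labels = paste(taxa[pr[1, ]], taxa[pr[2, ]], sep = "|"))
}

.perGeneScheme <- function(method, w, taxa) {
  w <- w / sum(w)
  new("WeightScheme", method = method, granularity = "per_gene",
      weights = w, taxa = taxa)
}

#' No-weight pooling weights (gene-length proportions)
#'
#' Each gene receives a weight proportional to its post-deletion length,
#' `w_h = L_h / sum_g L_g`. Pooling with these weights equals the
#' distance computed from the concatenation of all loci site-for-site,
#' which is why this baseline is called the no-weight method.
#'
#' @param x a [MultiLocusDataset-class] or a [GeneDistanceSet-class]
#'   (whose `L` slot already holds post-deletion lengths).
#' @return a [WeightScheme-class] with `method = "noweight"`.
#' @export
noweightWeights <- function(x) {
  if (is(x, "MultiLocusDataset")) {
    L <- locusLengths(x); tx <- x@taxa
  } else if (is(x, "GeneDistanceSet")) {
    L <- x@L; tx <- x@taxa
  } else stop("need a MultiLocusDataset or GeneDistanceSet")
  if (sum(L) == 0) stop("all loci have zero post-deletion length")
  .perGeneScheme("noweight", L, tx)
}

## Sampling variance of the smallest resolvable divergence for a locus of
## L sites: a comparison showing zero differences has a delta-method
## variance of exactly 0, which would hand such a gene *all* the weight
## under inverse-variance pooling and silence every informative gene. At
## the zero boundary we therefore charge it the variance of the smallest
## divergence L sites can resolve, p* = 1/(2L) (the same convention the
## distance estimators use at the saturation boundary). The resulting
## weight is still hundreds of times larger than a typical gene's, so the
## method's documented sensitivity to near-zero divergence is preserved.
.resolutionVariance <- function(L) {
  p <- 1 / (2 * L)
  p / (L * (1 - p))
}

#' Least-squares (per-pair inverse-variance) pooling weights
#'
#' For every unordered taxon pair, each gene is weighted by the reciprocal
#' of the sampling variance of its distance estimate for that pair,
#' normalized over genes within the pair: the minimum-variance linear
#' pooling when all genes estimate the same expected distance. A gene with
#' an exactly zero variance estimate for a pair (identical sequences) is
#' charged the variance of the smallest divergence its length can resolve,
#' so it dominates the pair strongly but not absolutely.
#'
#' @param gds a [GeneDistanceSet-class].
#' @return a [WeightScheme-class] with `method = "ls"`,
#'   `granularity = "per_gene_pair"`.
#' @export
lsWeights <- function(gds) {
  stopifnot(is(gds, "GeneDistanceSet"))
  pi <- .pairIndex(gds@taxa)
  H <- names(gds@k)
  W <- matrix(0, length(H), ncol(pi$idx), dimnames = list(H, pi$labels))
  Vmat <- vapply(H, function(h) gds@V[[h]][t(pi$idx)], numeric(ncol(pi$idx)))
  Vmat <- matrix(Vmat, ncol = length(H), dimnames = list(pi$labels, H))
  vfloor <- .resolutionVariance(gds@L[H])
  for (p in seq_len(ncol(pi$idx))) {
    v <- Vmat[p, ]
    zero <- v == 0
    if (any(zero)) v[zero] <- vfloor[zero]
    w <- 1 / v
    W[, p] <- w / sum(w)
  }
  new("WeightScheme", method = "ls", granularity = "per_gene_pair",
      weights = W, taxa = gds@taxa)
}

## Per-gene aggregates: unweighted means of k and V over unordered pairs.
.geneAggregates <- function(gds) {
  pi <- .pairIndex(gds@taxa)
  mu <- vapply(gds@k, function(K) mean(K[t(pi$idx)]), numeric(1))
  v <- vapply(gds@V, function(V) mean(V[t(pi$idx)]), numeric(1))
  list(mu = mu, v = v)
}

#' Modified Tajima-Takezaki pooling weights
#'
#' Assigns a single weight per gene, chosen to maximize the accuracy index
#' `A(w) = sum(w * mu) / sqrt(sum(w^2 * v))` of the pooled distance, where
#' `mu_h` and `v_h` are the per-gene means (over unordered taxon pairs) of
#' the distance estimates and of their sampling variances. The maximizer is
#' `w_h` proportional to `mu_h / v_h` (see [accuracyIndex()]). Genes with
#' no divergence (`mu_h = v_h = 0`) contribute neither signal nor noise and
#' receive weight zero; if every gene is such, the method falls back to
#' [noweightWeights()] with a warning.
#'
#' @param gds a [GeneDistanceSet-class].
#' @return a [WeightScheme-class] with `method = "mtt"`.
#' @export
mttWeights <- function(gds) {
  stopifnot(is(gds, "GeneDistanceSet"))
  ag <- .geneAggregates(gds)
  if (all(ag$mu == 0)) {
    warning("all per-gene mean distances are zero; falling back to no-weight")
    ws <- noweightWeights(gds)
    ws@method <- "mtt"
    return(ws)
  }
  w <- ifelse(ag$v > 0, ag$mu / ag$v, 0)
  if (all(w == 0)) {
    # divergence present but only in zero-variance genes: length-weight those
    w <- ifelse(ag$v == 0 & ag$mu > 0, gds@L, 0)
  }
  .perGeneScheme("mtt", w, gds@taxa)
}

#' Modified least-squares pooling weights
#'
#' Assigns a single weight per gene proportional to the reciprocal of the
#' gene's mean sampling variance over pairs, `w_h` proportional to
#' `1 / v_h`: the minimizer of the pooled variance `sum(w^2 * v)` on the
#' weight simplex. A nearly invariant gene has a tiny `v_h` and therefore a
#' large weight — this sensitivity to near-zero divergence is a documented
#' property of the method and is deliberately not damped by default. A
#' gene whose variance estimate is exactly zero for every pair (fully
#' invariant sequences) is charged the variance of the smallest divergence
#' its length can resolve, so its weight is very large but finite, with a
#' warning.
#'
#' @param gds a [GeneDistanceSet-class].
#' @return a [WeightScheme-class] with `method = "mls"`.
#' @export
mlsWeights <- function(gds) {
  stopifnot(is(gds, "GeneDistanceSet"))
  ag <- .geneAggregates(gds)
  v <- ag$v
  if (any(v == 0)) {
    warning("invariant gene(s) with zero variance estimate dominate: ",
            paste(names(v)[v == 0], collapse = ", "))
    v[v == 0] <- .resolutionVariance(gds@L[names(v)[v == 0]])
  }
  .perGeneScheme("mls", 1 / v, gds@taxa)
}

#' Compute pooling weights for a named method
#'
#' @param gds a [GeneDistanceSet-class].
#' @param method one of `"noweight"`, `"ls"`, `"mtt"`, `"mls"`.
#' @return a [WeightScheme-class].
#' @export
computeWeights <- function(gds, method = c("noweight", "ls", "mtt", "mls")) {
  method <- match.arg(method)
  switch(method,
    noweight = noweightWeights(gds),
    ls = lsWeights(gds),
    mtt = mttWeights(gds),
    mls = mlsWeights(gds))
}

#' Pool per-locus distances into one matrix
#'
#' `D(i, j) = sum_h w_h(i, j) * k(h, i, j)`, a convex combination of the
#' per-gene distances for each pair (weights are normalized per pair).
#'
#' @param gds a [GeneDistanceSet-class].
#' @param ws a [WeightScheme-class] covering every locus of `gds`.
#' @return a [PooledDistance-class].
#' @export
poolDistances <- function(gds, ws) {
  stopifnot(is(gds, "GeneDistanceSet"), is(ws, "WeightScheme"))
  H <- names(gds@k)
  n <- length(gds@taxa)
  D <- matrix(0, n, n, dimnames = list(gds@taxa, gds@taxa))
  if (ws@granularity == "per_gene") {
    if (!all(H %in% names(ws@weights)))
      stop("weight scheme is missing loci: ",
           paste(setdiff(H, names(ws@weights)), collapse = ", "))
    for (h in H) D <- D + ws@weights[[h]] * gds@k[[h]]
  } else {
    if (!all(H %in% rownames(ws@weights)))
      stop("weight scheme is missing loci: ",
           paste(setdiff(H, rownames(ws@weights)), collapse = ", "))
    pi <- .pairIndex(gds@taxa)
    for (p in seq_len(ncol(pi$idx))) {
      i <- pi$idx[1, p]; j <- pi$idx[2, p]
      kv <- vapply(H, function(h) gds@k[[h]][i, j], numeric(1))
      D[i, j] <- D[j, i] <- sum(ws@weights[H, p] * kv)
    }
  }
  new("PooledDistance", D = D, scheme = ws)
}

#' Accuracy index of a weighted pooled distance
#'
#' `A(w) = sum(w * mu) / sqrt(sum(w^2 * v))`: the expected pooled distance
#' divided by the standard deviation of its sampling error. Invariant to
#' rescaling of `w`; maximized over the simplex by `w` proportional to
#' `mu / v`.
#'
#' @param weights,mus,vars equal-length numeric vectors (per gene).
#' @return the accuracy index (single number).
#' @export
accuracyIndex <- function(weights, mus, vars) {
  stopifnot(length(weights) == length(mus), length(mus) == length(vars))
  if (all(weights == 0)) stop("all-zero weights")
  s2 <- sum(weights^2 * vars)
  if (s2 <= 0) stop("pooled variance is zero; accuracy index undefined")
  sum(weights * mus) / sqrt(s2)
}

#' Per-gene weight report
#'
#' @param gds a [GeneDistanceSet-class].
#' @param methods weighting methods to include.
#' @return data.frame with columns locus, length, method, weight (per-gene
#'   methods report the gene weight; the per-pair least-squares method
#'   reports the mean weight over pairs).
#' @export
weightReport <- function(gds, methods = c("noweight", "ls", "mtt", "mls")) {
  do.call(rbind, lapply(methods, function(m) {
    ws <- computeWeights(gds, m)
    w <- if (ws@granularity == "per_gene") ws@weights
         else rowMeans(ws@weights)
    data.frame(locus = names(gds@k), length = unname(gds@L),
               method = m, weight = unname(w[names(gds@k)]),
               stringsAsFactors = FALSE)
  }))
}
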