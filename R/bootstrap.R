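#' BootstrapResult: clade-support counts from site resampling
#'
#' @slot B replicate count.
#' @slot counts integer matrix, methods x queried clades; each entry is
#'   the number of replicates whose tree contained the clade.
#' @slot trees named character vector of full-data Newick trees per method.
#' @slot saturatedReplicates replicates in which at least one pairwise
#'   distance hit the saturation clamp.
#' @slot fallbackWarnings replicates in which a weighting method issued a
#'   degenerate-data warning (e.g. zero-variance genes).
#' @exportClass BootstrapResult
setClass("BootstrapResult",
  representation(B = "integer", counts = "matrix", trees = "character",
                 saturatedReplicates = "integer",
                 fallbackWarnings = "integer"))

setMethod("show", "BootstrapResult", function(object) {
  cat(sprintf("BootstrapResult: B = %d%s\n", object@B,
              if (object@saturatedReplicates > 0)
                sprintf(" (%d saturation-clamped)", object@saturatedReplicates)
              else ""))
  print(object@counts)
})

## stable 31-bit string hash, used to key per-locus resampling seeds by
## locus *name* so counts do not depend on locus order
.stringHash <- function(s) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 131 + c) %% 2147483647
  as.integer(h)
}

.muffleCount <- function(expr, counter_env) {
  withCallingHandlers(expr, warning = function(w) {
    counter_env$n <- counter_env$n + 1L
    invokeRestart("muffleWarning")
  })
}

.queryLabel <- function(q) paste(sort(q), collapse = ",")

#' Site-bootstrap clade support
#'
#' For each of `B` replicates, resamples alignment columns with
#' replacement independently within each locus (keeping each locus at its
#' own length), then recomputes distances, sampling variances, pooling
#' weights, the pooled matrix and the neighbor-joining tree, and counts
#' the replicates whose tree contains each queried clade. Weights are
#' recomputed from scratch inside every replicate since they depend on the
#' resampled estimates. Saturated distances inside replicates are clamped
#' (see [poissonDistance()]) so every replicate yields a tree.
#'
#' Reproducibility: the master `seed` spawns one child seed per replicate,
#' and within a replicate each locus' resampling stream is keyed by the
#' locus name, so results are invariant to locus order and any replicate
#' can be reproduced in isolation.
#'
#' @param dataset a [MultiLocusDataset-class] with >= 4 taxa.
#' @param model `"poisson"` or `"k2p"`.
#' @param method weighting method(s): subset of
#'   `c("noweight", "ls", "mtt", "mls")`. All methods see the same
#'   resampled data in each replicate (paired design).
#' @param query a character vector naming one clade, or a list of such
#'   vectors.
#' @param B number of bootstrap replicates.
#' @param seed master RNG seed.
#' @return a [BootstrapResult-class].
#' @export
bootstrapSupport <- function(dataset, model = c("poisson", "k2p"),
                             method = "noweight", query, B = 1000L,
                             seed = 1L) {
  stopifnot(is(dataset, "MultiLocusDataset"))
  model <- match.arg(model)
  if (length(dataset@taxa) < 4L)
    stop("bootstrap clade support needs at least 4 taxa")
  if (B < 1L) stop("B must be >= 1")
  methods <- match.arg(method, c("noweight", "ls", "mtt", "mls"),
                       several.ok = TRUE)
  if (!is.list(query)) query <- list(query)
  for (q in query) {
    bad <- setdiff(q, dataset@taxa)
    if (length(bad)) stop("unknown taxon in query: ", bad[1])
  }
  qlab <- vapply(query, .queryLabel, character(1))
  set.seed(seed)
  repSeeds <- sample.int(.Machine$integer.max - 1L, B)
  counts <- matrix(0L, length(methods), length(query),
                   dimnames = list(methods, qlab))
  wcount <- new.env(); wcount$n <- 0L
  nSat <- 0L
  lociOrder <- sort(names(dataset@loci))
  for (r in seq_len(B)) {
    res <- dataset
    for (h in lociOrder) {
      set.seed(as.integer((as.numeric(repSeeds[r]) + .stringHash(h)) %%
                            2147483647))
      sq <- res@loci[[h]]@seqs
      res@loci[[h]]@seqs <- sq[, sample.int(ncol(sq), ncol(sq),
                                            replace = TRUE), drop = FALSE]
    }
    gds <- distanceMatrices(res, model, clamp = TRUE)
    if (gds@saturated) nSat <- nSat + 1L
    for (m in methods) {
      ws <- .muffleCount(computeWeights(gds, m), wcount)
      tr <- neighborJoining(poolDistances(gds, ws))
      for (qi in seq_along(query))
        if (hasCluster(tr, query[[qi]]))
          counts[m, qi] <- counts[m, qi] + 1L
    }
  }
  # full-data trees per method
  gds0 <- distanceMatrices(dataset, model, clamp = TRUE)
  trees <- vapply(methods, function(m) {
    ws <- .muffleCount(computeWeights(gds0, m), wcount)
    writeNewick(neighborJoining(poolDistances(gds0, ws)))
  }, character(1))
  new("BootstrapResult", B = as.integer(B), counts = counts, trees = trees,
      saturatedReplicates = nSat, fallbackWarnings = wcount$n)
}

#' Tidy bootstrap report
#'
#' @param br a [BootstrapResult-class].
#' @return data.frame with columns method, query, B, count, proportion.
#' @export
bootstrapTable <- function(br) {
  stopifnot(is(br, "BootstrapResult"))
  g <- expand.grid(method = rownames(br@counts), query = colnames(br@counts),
                   stringsAsFactors = FALSE)
  g$B <- br@B
  g$count <- as.integer(br@counts[cbind(g$method, g$query)])
  g$proportion <- g$count / br@B
  g
}
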