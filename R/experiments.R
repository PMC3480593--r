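## Wilson score interval half-width at confidence level `conf`
.wilsonHalfWidth <- function(x, n, conf = 0.99) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
}

#' Proportion-correct simulation experiment
#'
#' Runs `replicates` independent simulation trials at one parameter
#' setting. Each trial simulates a multi-locus dataset, computes per-locus
#' distances and variances, then — for every weighting method, on the same
#' simulated data (paired design) — pools the distances, reconstructs the
#' neighbor-joining tree and compares its unrooted topology with the
#' generating tree. Reports PC (the proportion of trials recovering the
#' generating topology exactly), its 99% Wilson confidence half-width,
#' and the mean partition distance dT.
#'
#' @param cfg a [simConfig()].
#' @param methods weighting methods to compare.
#' @param replicates number of simulation trials.
#' @param seed master RNG seed.
#' @return data.frame with one row per method: `method`, `replicates`,
#'   `correct`, `pc`, `ci99`, `mean_dT`, `saturated_replicates`,
#'   `degenerate_warnings`; the configuration is attached as
#'   `attr(, "config")`.
#' @export
runPCExperiment <- function(cfg, methods = c("noweight", "ls", "mtt", "mls"),
                            replicates = 500L, seed = 1L) {
  stopifnot(inherits(cfg, "SimConfig"), replicates >= 1L)
  methods <- match.arg(methods, c("noweight", "ls", "mtt", "mls"),
                       several.ok = TRUE)
  model <- if (cfg$alphabet == "AA") "poisson" else "k2p"
  set.seed(seed)
  repSeeds <- sample.int(.Machine$integer.max - 1L, replicates)
  correct <- setNames(integer(length(methods)), methods)
  dTsum <- setNames(numeric(length(methods)), methods)
  nSat <- 0L
  wcount <- new.env(); wcount$n <- 0L
  trueTree <- cfg$tree
  for (r in seq_len(replicates)) {
    ds <- simulateDataset(cfg, seed = repSeeds[r])
    gds <- distanceMatrices(ds, model, clamp = TRUE)
    if (gds@saturated) nSat <- nSat + 1L
    for (m in methods) {
      ws <- .muffleCount(computeWeights(gds, m), wcount)
      tr <- neighborJoining(poolDistances(gds, ws))
      d <- partitionDistance(tr, trueTree)
      dTsum[m] <- dTsum[m] + d
      if (d == 0L) correct[m] <- correct[m] + 1L
    }
  }
  out <- data.frame(
    method = methods,
    replicates = replicates,
    correct = as.integer(correct),
    pc = unname(correct) / replicates,
    ci99 = .wilsonHalfWidth(unname(correct), replicates),
    mean_dT = unname(dTsum) / replicates,
    saturated_replicates = nSat,
    degenerate_warnings = wcount$n,
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "config") <- cfg
  out
}

#' Run a PC experiment over a parameter grid
#'
#' Repeats [runPCExperiment()] while varying the gamma shape `a` (rate
#' variation among loci) or the mean rate `u`, mirroring the two study
#' designs: `u` fixed with `a` swept, and `a` fixed with `u` swept.
#'
#' @param baseCfg a [simConfig()] supplying all non-varied parameters.
#' @param vary `"a"` or `"u"`.
#' @param values grid values for the varied parameter.
#' @param methods,replicates,seed passed to [runPCExperiment()]; each grid
#'   point gets an independent child seed of `seed`.
#' @return data.frame: grid columns `a` and `u`, plus the
#'   [runPCExperiment()] columns.
#' @export
runGrid <- function(baseCfg, vary = c("a", "u"), values,
                    methods = c("noweight", "ls", "mtt", "mls"),
                    replicates = 500L, seed = 1L) {
  vary <- match.arg(vary)
  if (length(values) == 0L) stop("empty grid")
  set.seed(seed)
  gridSeeds <- sample.int(.Machine$integer.max - 1L, length(values))
  rows <- lapply(seq_along(values), function(i) {
    cfg <- baseCfg
    cfg[[vary]] <- values[i]
    res <- runPCExperiment(cfg, methods = methods, replicates = replicates,
                           seed = gridSeeds[i])
    cbind(data.frame(a = cfg$a, u = cfg$u), res)
  })
  do.call(rbind, rows)
}

#' Method-of-moments estimate of the among-locus gamma shape
#'
#' Given per-gene distance estimates for one taxon pair, estimates the
#' gamma shape governing among-locus rate variation as `a_hat = m^2 / v`,
#' where `m` and `v` are the (unrounded) sample mean and sample variance
#' of the estimates; this inverts V[u(h)] = u^2 / a.
#'
#' @param k numeric vector of per-gene distance estimates (>= 2 genes).
#' @return the shape estimate `a_hat`.
#' @export
estimateGammaShape <- function(k) {
  if (length(k) < 2L) stop("need estimates from at least 2 genes")
  v <- var(k)
  if (v == 0)
    stop("no variation among per-gene estimates (shape effectively infinite)")
  mean(k)^2 / v
}

#' Per-pair summary of per-gene distances and implied gamma shape
#'
#' @param gds a [GeneDistanceSet-class] with >= 2 loci.
#' @return data.frame with one row per unordered taxon pair: `taxon_i`,
#'   `taxon_j`, `mean_k` and `var_k` over genes, and `a_hat` from
#'   [estimateGammaShape()] (NA where the variance is zero).
#' @export
pairGammaTable <- function(gds) {
  stopifnot(is(gds, "GeneDistanceSet"))
  pi <- .pairIndex(gds@taxa)
  rows <- lapply(seq_len(ncol(pi$idx)), function(p) {
    i <- pi$idx[1, p]; j <- pi$idx[2, p]
    ks <- vapply(gds@k, function(K) K[i, j], numeric(1))
    data.frame(taxon_i = gds@taxa[i], taxon_j = gds@taxa[j],
               mean_k = mean(ks), var_k = var(ks),
               a_hat = if (var(ks) > 0) estimateGammaShape(ks) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Multi-gene bootstrap application driver
#'
#' The full application workflow on user-supplied aligned gene files (or
#' an assembled dataset): reconstructs the full-data neighbor-joining tree
#' under each weighting method, measures bootstrap support for a queried
#' clade, and reports the per-gene weights and the per-pair distance
#' summaries feeding [estimateGammaShape()]. Selected loci can be dropped
#' beforehand to repeat an analysis without them.
#'
#' @param x a manifest path (see [readLocusManifest()]) or a
#'   [MultiLocusDataset-class].
#' @param model `"poisson"` or `"k2p"`.
#' @param methods weighting methods to run.
#' @param query clade to score, as a character vector of taxon labels.
#' @param B bootstrap replicates.
#' @param seed master RNG seed.
#' @param exclude locus names to drop before analysis.
#' @return list of class `"BootstrapStudy"`: `counts` (tidy bootstrap
#'   table), `trees` (named Newick strings), `weights` (per-gene weight
#'   report), `gamma` (per-pair summary), `result` (the underlying
#'   [BootstrapResult-class]).
#' @export
runBootstrapStudy <- function(x, model = c("poisson", "k2p"),
                              methods = c("noweight", "ls", "mtt", "mls"),
                              query, B = 1000L, seed = 1L,
                              exclude = character()) {
  model <- match.arg(model)
  dataset <- if (is.character(x)) {
    readLocusManifest(x, exclude = exclude)
  } else {
    if (length(exclude)) excludeLoci(x, exclude) else x
  }
  br <- bootstrapSupport(dataset, model, method = methods, query = query,
                         B = B, seed = seed)
  wcount <- new.env(); wcount$n <- 0L
  gds <- distanceMatrices(dataset, model, clamp = TRUE)
  out <- list(counts = bootstrapTable(br), trees = br@trees,
              weights = .muffleCount(weightReport(gds, methods), wcount),
              gamma = pairGammaTable(gds), result = br)
  class(out) <- "BootstrapStudy"
  out
}

#' @export
print.BootstrapStudy <- function(x, ...) {
  cat("BootstrapStudy\n")
  print(x$counts)
  invisible(x)
}
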