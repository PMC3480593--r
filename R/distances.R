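#' Proportion of differing sites between two gap-free rows
#'
#' @param row_i,row_j character vectors (one residue per element) or single
#'   strings of equal length, already filtered by [completeDeletion()].
#' @return list with `p` (proportion of differing sites) and `L` (sites).
#' @export
pDistance <- function(row_i, row_j) {
  if (length(row_i) == 1L && nchar(row_i[1]) > 1L) row_i <- strsplit(row_i, "")[[1]]
  if (length(row_j) == 1L && nchar(row_j[1]) > 1L) row_j <- strsplit(row_j, "")[[1]]
  if (length(row_i) != length(row_j)) stop("rows differ in length")
  L <- length(row_i)
  if (L == 0L) stop("no comparable sites")
  list(p = sum(row_i != row_j) / L, L = L)
}

#' Poisson-corrected distance with delta-method variance
#'
#' For amino-acid sequences the number of substitutions per site is
#' estimated as `k = -log(1 - p)` from the proportion `p` of differing
#' sites; its sampling variance follows from the binomial variance of `p`
#' by the delta method: `V = p / (L * (1 - p))`.
#'
#' @param p proportion of differing sites in `[0, 1)`.
#' @param L number of compared sites.
#' @param clamp if `TRUE`, a saturated comparison (`p >= 1`) is clamped so
#'   that `1 - p = 1/(2L)` (the smallest resolvable non-identity) instead
#'   of erroring; used inside simulation replicates where a finite matrix
#'   is required. The result carries `saturated = TRUE`.
#' @return list with `k`, `V`, `L`, `saturated`.
#' @export
poissonDistance <- function(p, L, clamp = FALSE) {
  if (L < 1L) stop("no comparable sites")
  saturated <- FALSE
  if (p >= 1) {
    if (!clamp)
      stop(sprintf("saturated distance: p = %.4f admits no Poisson correction", p))
    p <- 1 - 1 / (2 * L)
    saturated <- TRUE
  }
  list(k = -log(1 - p), V = p / (L * (1 - p)), L = L, saturated = saturated)
}

#' Transition and transversion proportions between two DNA rows
#'
#' Transitions are A<->G and C<->T; every other difference is a
#' transversion. Rows must be gap-free ACGT (run [completeDeletion()]
#' first).
#'
#' @inheritParams pDistance
#' @return list with `P` (transition proportion), `Q` (transversion
#'   proportion) and `L`.
#' @export
k2pCounts <- function(row_i, row_j) {
  if (length(row_i) == 1L && nchar(row_i[1]) > 1L) row_i <- strsplit(row_i, "")[[1]]
  if (length(row_j) == 1L && nchar(row_j[1]) > 1L) row_j <- strsplit(row_j, "")[[1]]
  if (length(row_i) != length(row_j)) stop("rows differ in length")
  L <- length(row_i)
  if (L == 0L) stop("no comparable sites")
  ok <- c("A", "C", "G", "T")
  if (!all(row_i %in% ok) || !all(row_j %in% ok))
    stop("non-ACGT character; apply completeDeletion() first")
  diff <- row_i != row_j
  pur <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  ts <- diff & (pur[row_i] == pur[row_j])
  list(P = sum(ts) / L, Q = sum(diff & !ts) / L, L = L)
}

#' Kimura 2-parameter distance with delta-method variance
#'
#' `k = -log(1 - 2P - Q)/2 - log(1 - 2Q)/4`, with the classical
#' delta-method variance
#' `V = (c1^2 P + c3^2 Q - (c1 P + c3 Q)^2) / L`,
#' `c1 = 1/(1 - 2P - Q)`, `c2 = 1/(1 - 2Q)`, `c3 = (c1 + c2)/2`.
#'
#' @param P transition proportion.
#' @param Q transversion proportion.
#' @param L number of compared sites.
#' @param clamp if `TRUE`, a non-positive logarithm argument is clamped to
#'   `1/(2L)` rather than erroring (see [poissonDistance()]).
#' @return list with `k`, `V`, `L`, `saturated`.
#' @export
k2pDistance <- function(P, Q, L, clamp = FALSE) {
  if (L < 1L) stop("no comparable sites")
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  saturated <- FALSE
  if (w1 <= 0 || w2 <= 0) {
    if (!clamp)
      stop(sprintf(
        "saturated distance: P = %.4f, Q = %.4f leave a non-positive log argument",
        P, Q))
    floorv <- 1 / (2 * L)
    if (w1 <= 0) w1 <- floorv
    if (w2 <= 0) w2 <- floorv
    saturated <- TRUE
  }
  c1 <- 1 / w1
  c2 <- 1 / w2
  c3 <- (c1 + c2) / 2
  k <- -log(w1) / 2 - log(w2) / 4
  V <- (c1^2 * P + c3^2 * Q - (c1 * P + c3 * Q)^2) / L
  list(k = k, V = max(V, 0), L = L, saturated = saturated)
}

#' Per-locus pairwise distance and variance matrices
#'
#' Computes, for every locus of a dataset and every unordered taxon pair,
#' the evolutionary distance `k(h, i, j)` and its sampling variance
#' `V[k(h, i, j)]` under the chosen model: Poisson-corrected distances for
#' amino-acid loci, Kimura 2-parameter distances for DNA loci. Distances
#' use each locus' own post-deletion length, so `L` differs across loci.
#'
#' @param dataset a [MultiLocusDataset-class] (already complete-deleted by
#'   [assembleDataset()]).
#' @param model `"poisson"` (AA) or `"k2p"` (DNA).
#' @param clamp saturation policy: clamp log arguments inside replicates
#'   (see [poissonDistance()]); default `FALSE` errors on saturation.
#' @return a [GeneDistanceSet-class].
#' @export
distanceMatrices <- function(dataset, model = c("poisson", "k2p"),
                             clamp = FALSE) {
  stopifnot(is(dataset, "MultiLocusDataset"))
  model <- match.arg(model)
  need <- if (model == "poisson") "AA" else "DNA"
  tx <- dataset@taxa
  n <- length(tx)
  anySat <- FALSE
  kList <- list(); vList <- list(); Lvec <- numeric()
  for (h in names(dataset@loci)) {
    aln <- dataset@loci[[h]]
    if (aln@alphabet != need)
      stop("model '", model, "' requires ", need, " sequences but locus '",
           h, "' is ", aln@alphabet)
    L <- ncol(aln@seqs)
    if (L == 0L)
      stop("locus '", h, "' has no comparable sites after complete deletion")
    K <- matrix(0, n, n, dimnames = list(tx, tx))
    V <- K
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      ri <- aln@seqs[i, ]; rj <- aln@seqs[j, ]
      est <- if (model == "poisson") {
        poissonDistance(sum(ri != rj) / L, L, clamp = clamp)
      } else {
        ct <- k2pCounts(ri, rj)
        k2pDistance(ct$P, ct$Q, L, clamp = clamp)
      }
      K[i, j] <- K[j, i] <- est$k
      V[i, j] <- V[j, i] <- est$V
      anySat <- anySat || est$saturated
    }
    kList[[h]] <- K; vList[[h]] <- V; Lvec[h] <- L
  }
  new("GeneDistanceSet", k = kList, V = vList, L = Lvec, taxa = tx,
      model = model, saturated = anySat)
}

#' Tidy per-locus distance table
#'
#' @param gds a [GeneDistanceSet-class].
#' @return data.frame with columns locus, taxon_i, taxon_j, k, V, L.
#' @export
distanceTable <- function(gds) {
  stopifnot(is(gds, "GeneDistanceSet"))
  tx <- gds@taxa
  pr <- combn(length(tx), 2L)
  do.call(rbind, lapply(names(gds@k), function(h) {
    data.frame(locus = h,
               taxon_i = tx[pr[1, ]], taxon_j = tx[pr[2, ]],
               k = gds@k[[h]][t(pr)], V = gds@V[[h]][t(pr)],
               L = unname(gds@L[h]), stringsAsFactors = FALSE)
  }))
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param D symmetric numeric matrix with taxon dimnames, or a
#'   [PooledDistance-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePhylipMatrix <- function(D, path) {
  if (is(D, "PooledDistance")) D <- D@D
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(D)), con)
  for (i in seq_len(nrow(D)))
    writeLines(paste0(formatC(rownames(D)[i], width = -10),
                      paste(sprintf("%.6f", D[i, ]), collapse = "  ")), con)
  invisible(path)
}
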