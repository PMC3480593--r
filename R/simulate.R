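#' Built-in clock-like model trees
#'
#' Two ultrametric 8-taxon trees in time units T, with all internal
#' branches 0.1 T. Tree `"A"` is the fully asymmetric (caterpillar) tree
#' with cherry depth 0.1 T and root depth 0.7 T, so its longest
#' tip-to-tip path is 1.4 T. Tree `"B"` is the fully balanced tree with
#' every branch 0.1 T (root depth 0.3 T, longest path 0.6 T). When a
#' branch has length t, the expected number of substitutions per site on
#' it is t * u(h) for a locus with rate u(h).
#'
#' @param which `"A"` (asymmetric) or `"B"` (symmetric).
#' @return an `ape::phylo` with tip labels `t1..t8`.
#' @export
defaultTree <- function(which = c("A", "B")) {
  which <- match.arg(which)
  txt <- if (which == "A") {
    paste0("(((((((t1:0.1,t2:0.1):0.1,t3:0.2):0.1,t4:0.3):0.1,",
           "t5:0.4):0.1,t6:0.5):0.1,t7:0.6):0.1,t8:0.7);")
  } else {
    paste0("(((t1:0.1,t2:0.1):0.1,(t3:0.1,t4:0.1):0.1):0.1,",
           "((t5:0.1,t6:0.1):0.1,(t7:0.1,t8:0.1):0.1):0.1);")
  }
  parseNewick(txt)
}

#' Gamma-distributed per-locus substitution rates
#'
#' Draws independent rates u(h) from a gamma distribution with shape `a`
#' and mean `u` (rate parameter b = a/u), so E[u(h)] = u and
#' V[u(h)] = u^2 / a. `a = Inf` means no rate variation: every locus gets
#' exactly `u`.
#'
#' @param n number of loci.
#' @param u mean rate per site per T (> 0).
#' @param a gamma shape (> 0, or `Inf`).
#' @return numeric vector of `n` rates.
#' @export
sampleLocusRates <- function(n, u, a) {
  if (n < 1L) stop("n must be >= 1")
  if (u <= 0) stop("mean rate u must be positive")
  if (is.infinite(a)) return(rep(u, n))
  if (a <= 0) stop("gamma shape a must be positive (or Inf)")
  rgamma(n, shape = a, rate = a / u)
}

## integer-state mutation along one branch: m ~ Pois(t * rate) events per
## site; each event replaces the state by one of the others, uniformly for
## the 20-state model, with transition:transversion ratio kappa for DNA.
.mutateAA <- function(s, expSub) {
  m <- rpois(length(s), expSub)
  mx <- max(m)
  j <- 1L
  while (j <= mx) {
    act <- which(m >= j)
    s[act] <- (s[act] - 1L + sample.int(19L, length(act), replace = TRUE)) %% 20L + 1L
    j <- j + 1L
  }
  s
}

.TS_PARTNER <- c(2L, 1L, 4L, 3L)   # states 1=A, 2=G, 3=C, 4=T

.mutateDNA <- function(s, expSub, kappa) {
  pTs <- kappa / (kappa + 2)
  m <- rpois(length(s), expSub)
  mx <- max(m)
  j <- 1L
  while (j <= mx) {
    act <- which(m >= j)
    ts <- runif(length(act)) < pTs
    ai <- act[ts]
    s[ai] <- .TS_PARTNER[s[ai]]
    av <- act[!ts]
    if (length(av)) {
      # purines (1,2) go to a pyrimidine (3,4) and vice versa
      base <- ifelse(s[av] <= 2L, 2L, 0L)
      s[av] <- base + sample.int(2L, length(av), replace = TRUE)
    }
    j <- j + 1L
  }
  s
}

#' Simulate one locus along a tree
#'
#' The root sequence is drawn uniformly over the alphabet; along each
#' branch of length t (in T units) every site accumulates a
#' Poisson(t * rate) number of substitution events. Amino acids follow the
#' 20-state equal-rates model (each event moves to one of the other 19
#' states uniformly); DNA follows the Kimura 2-parameter process with a
#' transition : single-transversion-type rate ratio `kappa` (total rate
#' alpha + 2 beta = `rate`, alpha/beta = `kappa`).
#'
#' @param tree `ape::phylo` with branch lengths in T units.
#' @param rate substitutions per site per T (> 0).
#' @param length number of sites (>= 1).
#' @param alphabet `"AA"` or `"DNA"`.
#' @param kappa transition/transversion rate ratio (DNA only).
#' @param name locus label.
#' @return a [LocusAlignment-class] over the tree's tips.
#' @export
evolveSequences <- function(tree, rate, length, alphabet = c("AA", "DNA"),
                            kappa = 4, name = "locus") {
  alphabet <- match.arg(alphabet)
  if (rate <= 0) stop("rate must be positive")
  if (length < 1L) stop("length must be >= 1")
  stopifnot(inherits(tree, "phylo"))
  tree <- ape::reorder.phylo(tree, "cladewise")
  ns <- if (alphabet == "AA") 20L else 4L
  chars <- if (alphabet == "AA") .alphabetChars("AA") else c("A", "G", "C", "T")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[root]] <- sample.int(ns, length, replace = TRUE)
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    t <- tree$edge.length[e]
    s <- seqs[[par]]
    if (t > 0) {
      s <- if (alphabet == "AA") .mutateAA(s, t * rate)
           else .mutateDNA(s, t * rate, kappa)
    }
    seqs[[child]] <- s
  }
  m <- matrix("", ntip, length, dimnames = list(tree$tip.label, NULL))
  for (i in seq_len(ntip)) m[i, ] <- chars[seqs[[i]]]
  new("LocusAlignment", name = name, alphabet = alphabet, seqs = m)
}

#' Simulation configuration
#'
#' Bundles one grid point of the simulation study: the model tree, the
#' number of loci and their lengths, the alphabet, the mean rate `u` and
#' gamma shape `a` of among-locus rate variation, the DNA
#' transition/transversion ratio, and whether evolution is clock-like.
#' Defaults mirror the study conditions: 10 loci of 500 sites each on a
#' built-in model tree.
#'
#' @param tree `ape::phylo` (branch lengths in T units) or `"A"` / `"B"`
#'   for [defaultTree()].
#' @param nLoci number of loci.
#' @param locusLengths per-locus site counts, recycled to `nLoci`.
#' @param alphabet `"AA"` or `"DNA"`.
#' @param u mean substitution rate per site per T.
#' @param a gamma shape of among-locus rate variation (`Inf` = none).
#' @param kappa DNA transition/transversion rate ratio.
#' @param clock if `FALSE`, each branch of each locus is multiplied by an
#'   independent lognormal factor with mean 1 and log-sd `sigma`.
#' @param sigma log-sd of the non-clock branch multipliers.
#' @return a `SimConfig` object.
#' @export
simConfig <- function(tree = "A", nLoci = 10L, locusLengths = 500L,
                      alphabet = c("AA", "DNA"), u = 0.5, a = 0.5,
                      kappa = 4, clock = TRUE, sigma = 0.5) {
  alphabet <- match.arg(alphabet)
  if (is.character(tree)) tree <- defaultTree(tree)
  stopifnot(inherits(tree, "phylo"), nLoci >= 1L, u > 0,
            is.infinite(a) || a > 0)
  lens <- as.integer(rep_len(locusLengths, nLoci))
  if (any(lens < 1L)) stop("locus lengths must be >= 1")
  structure(list(tree = tree, nLoci = as.integer(nLoci),
                 locusLengths = lens, alphabet = alphabet, u = u, a = a,
                 kappa = kappa, clock = clock, sigma = sigma),
            class = "SimConfig")
}

#' @export
print.SimConfig <- function(x, ...) {
  cat(sprintf(
    "SimConfig: %d tips, %d %s loci (%d-%d sites), u = %g, a = %g%s\n",
    length(x$tree$tip.label), x$nLoci, x$alphabet,
    min(x$locusLengths), max(x$locusLengths), x$u, x$a,
    if (x$clock) "" else sprintf(", non-clock (sigma = %g)", x$sigma)))
  invisible(x)
}

#' Simulate a multi-locus dataset
#'
#' Draws one gamma rate per locus with [sampleLocusRates()] and evolves
#' each locus independently on the shared tree with [evolveSequences()].
#' In non-clock mode every branch of every locus is additionally scaled by
#' an independent lognormal factor with mean 1.
#'
#' @param cfg a [simConfig()].
#' @param seed optional integer seed for reproducibility.
#' @return a [MultiLocusDataset-class].
#' @export
simulateDataset <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "SimConfig"))
  if (!is.null(seed)) set.seed(seed)
  rates <- sampleLocusRates(cfg$nLoci, cfg$u, cfg$a)
  nms <- sprintf("locus%02d", seq_len(cfg$nLoci))
  loci <- vector("list", cfg$nLoci)
  for (h in seq_len(cfg$nLoci)) {
    tr <- cfg$tree
    if (!cfg$clock)
      tr$edge.length <- tr$edge.length *
        rlnorm(length(tr$edge.length), -cfg$sigma^2 / 2, cfg$sigma)
    loci[[h]] <- evolveSequences(tr, rates[h], cfg$locusLengths[h],
                                 cfg$alphabet, cfg$kappa, name = nms[h])
  }
  names(loci) <- nms
  new("MultiLocusDataset", loci = loci, taxa = cfg$tree$tip.label)
}

#' Write a simulated dataset as per-locus FASTA plus a manifest
#'
#' @param dataset a [MultiLocusDataset-class].
#' @param dir output directory (created if missing).
#' @param tree optional true tree, written as `true_tree.nwk`.
#' @return the manifest path, invisibly.
#' @export
writeDataset <- function(dataset, dir, tree = NULL) {
  stopifnot(is(dataset, "MultiLocusDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- character()
  for (h in names(dataset@loci)) {
    f <- file.path(dir, paste0(h, ".fasta"))
    writeLocusFasta(dataset@loci[[h]], f)
    rows <- c(rows, paste(h, paste0(h, ".fasta"),
                          dataset@loci[[h]]@alphabet, sep = "\t"))
  }
  manifest <- file.path(dir, "manifest.tsv")
  writeLines(rows, manifest)
  if (!is.null(tree)) writeNewick(tree, file.path(dir, "true_tree.nwk"))
  invisible(manifest)
}
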