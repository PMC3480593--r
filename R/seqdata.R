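#' Construct a LocusAlignment from sequences
#'
#' @param seqs named character vector of equal-length sequence strings, or a
#'   character matrix with one residue per cell and taxon rownames.
#' @param name locus label.
#' @param alphabet `"AA"` or `"DNA"`.
#' @return a [LocusAlignment-class].
#' @examples
#' locusAlignment(c(a = "ACGT", b = "ACGA"), name = "gene1",
#'                alphabet = "DNA")
#' @export
locusAlignment <- function(seqs, name = "locus", alphabet = c("AA", "DNA")) {
  alphabet <- match.arg(alphabet)
  if (is.matrix(seqs)) {
    m <- seqs
  } else {
    if (is.null(names(seqs))) stop("sequences must be named by taxon")
    nc <- nchar(seqs)
    if (length(unique(nc)) > 1L) {
      bad <- names(seqs)[which(nc != nc[1])[1]]
      stop("ragged alignment: record '", bad, "' has length ",
           nchar(seqs[[bad]]), ", expected ", nc[1])
    }
    m <- do.call(rbind, strsplit(seqs, ""))
    rownames(m) <- names(seqs)
  }
  if (nrow(m) && ncol(m)) m[] <- toupper(m)
  new("LocusAlignment", name = name, alphabet = alphabet, seqs = m)
}

#' Read one locus alignment from a FASTA file
#'
#' Reads a multi-record FASTA file holding one aligned gene (all records the
#' same length), preserving record order and uppercasing residues. Record
#' names are truncated at the first whitespace.
#'
#' @param path FASTA file path.
#' @param alphabet `"AA"` or `"DNA"`.
#' @param name locus label; defaults to the file name without extension.
#' @return a [LocusAlignment-class].
#' @export
readLocusFasta <- function(path, alphabet = c("AA", "DNA"), name = NULL) {
  alphabet <- match.arg(alphabet)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  labs <- sub("\\s.*$", "", names(ss))
  w <- Biostrings::width(ss)
  if (length(unique(w)) > 1L) {
    bad <- labs[which(w != w[1])[1]]
    stop("ragged alignment in ", path, ": record '", bad, "' has length ",
         w[which(labs == bad)[1]], ", expected ", w[1])
  }
  locusAlignment(setNames(as.character(ss), labs), name = name,
                 alphabet = alphabet)
}

#' Write a locus alignment to FASTA
#'
#' @param aln a [LocusAlignment-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeLocusFasta <- function(aln, path) {
  stopifnot(is(aln, "LocusAlignment"))
  s <- apply(aln@seqs, 1L, paste, collapse = "")
  ss <- Biostrings::BStringSet(s)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Complete-deletion filtering of gapped or ambiguous columns
#'
#' Keeps exactly the columns in which every taxon carries an unambiguous
#' residue of the locus alphabet; any column holding a gap (`-`, `.`) or an
#' ambiguity code (`N`, `X`, `?`, IUPAC degeneracies, ...) in any taxon is
#' dropped. Column order is preserved. A zero-length result is allowed;
#' distance computation rejects it downstream.
#'
#' @param aln a [LocusAlignment-class].
#' @return the filtered [LocusAlignment-class].
#' @export
completeDeletion <- function(aln) {
  stopifnot(is(aln, "LocusAlignment"))
  ok <- .alphabetChars(aln@alphabet)
  if (ncol(aln@seqs) == 0L) return(aln)
  keep <- colSums(matrix(!(aln@seqs %in% ok), nrow = nrow(aln@seqs))) == 0L
  aln@seqs <- aln@seqs[, keep, drop = FALSE]
  aln
}

#' Assemble a multi-locus dataset over a shared taxon set
#'
#' Subsets and reorders every locus to the requested taxa, then applies
#' [completeDeletion()] per locus. Deletion runs after subsetting, so
#' removing a taxon can rescue columns that were gapped only in it.
#'
#' @param loci list of [LocusAlignment-class] objects.
#' @param taxa optional taxon subset / ordering; default: the taxon list of
#'   the first locus.
#' @return a [MultiLocusDataset-class].
#' @export
assembleDataset <- function(loci, taxa = NULL) {
  if (length(loci) < 1L) stop("at least one locus is required")
  stopifnot(all(vapply(loci, is, logical(1), "LocusAlignment")))
  if (is.null(taxa)) taxa <- rownames(loci[[1]]@seqs)
  taxa <- as.character(taxa)
  out <- lapply(loci, function(l) {
    miss <- setdiff(taxa, rownames(l@seqs))
    if (length(miss))
      stop("taxon ", miss[1], " absent from locus ", l@name)
    l@seqs <- l@seqs[taxa, , drop = FALSE]
    completeDeletion(l)
  })
  names(out) <- vapply(out, function(l) l@name, character(1))
  new("MultiLocusDataset", loci = out, taxa = taxa)
}

#' Read a locus manifest
#'
#' A manifest is a headerless tab-separated file with one locus per line:
#' `name<TAB>path<TAB>alphabet`. Relative paths are resolved against the
#' manifest's directory.
#'
#' @param path manifest file.
#' @param exclude character vector of locus names to drop before assembly
#'   (e.g. to repeat an analysis without selected genes).
#' @param taxa optional shared taxon subset passed to [assembleDataset()].
#' @return a [MultiLocusDataset-class].
#' @export
readLocusManifest <- function(path, exclude = character(), taxa = NULL) {
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           col.names = c("name", "path", "alphabet"),
                           stringsAsFactors = FALSE)
  tab <- tab[!tab$name %in% exclude, , drop = FALSE]
  if (nrow(tab) == 0L) stop("manifest holds no loci after exclusion")
  dir <- dirname(path)
  loci <- lapply(seq_len(nrow(tab)), function(i) {
    p <- tab$path[i]
    if (!file.exists(p)) p <- file.path(dir, tab$path[i])
    readLocusFasta(p, alphabet = tab$alphabet[i], name = tab$name[i])
  })
  assembleDataset(loci, taxa = taxa)
}

#' Drop loci from a dataset
#'
#' @param dataset a [MultiLocusDataset-class].
#' @param exclude locus names to remove.
#' @return the reduced [MultiLocusDataset-class].
#' @export
excludeLoci <- function(dataset, exclude) {
  stopifnot(is(dataset, "MultiLocusDataset"))
  unknown <- setdiff(exclude, names(dataset@loci))
  if (length(unknown)) stop("unknown locus: ", unknown[1])
  keep <- setdiff(names(dataset@loci), exclude)
  if (length(keep) == 0L) stop("exclusion would remove every locus")
  new("MultiLocusDataset", loci = dataset@loci[keep], taxa = dataset@taxa)
}
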