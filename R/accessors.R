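#' Accessors for locipool classes
#'
#' `taxa()` returns taxon labels; `loci()` the per-locus alignments of a
#' dataset; `locusNames()` and `locusLengths()` per-locus metadata;
#' `alignmentLength()` the number of columns of one alignment;
#' `distanceMatrix()` / `varianceMatrix()` one locus' matrices from a
#' [GeneDistanceSet-class]; `weightMethod()` and `weights()` describe a
#' [WeightScheme-class]; `pooledMatrix()` extracts the matrix of a
#' [PooledDistance-class].
#'
#' @param object,x a locipool object.
#' @param locus locus name (single string).
#' @param ... unused.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("taxa", function(object) standardGeneric("taxa"))
#' @rdname accessors
#' @export
setMethod("taxa", "LocusAlignment", function(object) rownames(object@seqs))
#' @rdname accessors
#' @export
setMethod("taxa", "MultiLocusDataset", function(object) object@taxa)
#' @rdname accessors
#' @export
setMethod("taxa", "GeneDistanceSet", function(object) object@taxa)
#' @rdname accessors
#' @export
setMethod("taxa", "PooledDistance", function(object) rownames(object@D))

#' @rdname accessors
#' @export
setGeneric("loci", function(object) standardGeneric("loci"))
#' @rdname accessors
#' @export
setMethod("loci", "MultiLocusDataset", function(object) object@loci)

#' @rdname accessors
#' @export
setGeneric("locusNames", function(object) standardGeneric("locusNames"))
#' @rdname accessors
#' @export
setMethod("locusNames", "MultiLocusDataset",
          function(object) names(object@loci))
#' @rdname accessors
#' @export
setMethod("locusNames", "GeneDistanceSet", function(object) names(object@k))

#' @rdname accessors
#' @export
setGeneric("locusLengths", function(object) standardGeneric("locusLengths"))
#' @rdname accessors
#' @export
setMethod("locusLengths", "MultiLocusDataset", function(object)
  vapply(object@loci, function(l) ncol(l@seqs), numeric(1)))
#' @rdname accessors
#' @export
setMethod("locusLengths", "GeneDistanceSet", function(object) object@L)

#' @rdname accessors
#' @export
setGeneric("alignmentLength",
           function(object) standardGeneric("alignmentLength"))
#' @rdname accessors
#' @export
setMethod("alignmentLength", "LocusAlignment",
          function(object) ncol(object@seqs))

#' @rdname accessors
#' @export
setGeneric("alphabet", function(object) standardGeneric("alphabet"))
#' @rdname accessors
#' @export
setMethod("alphabet", "LocusAlignment", function(object) object@alphabet)

#' @rdname accessors
#' @export
sequenceMatrix <- function(x) {
  stopifnot(is(x, "LocusAlignment"))
  x@seqs
}

#' @rdname accessors
#' @export
setGeneric("distanceMatrix",
           function(object, locus) standardGeneric("distanceMatrix"))
#' @rdname accessors
#' @export
setMethod("distanceMatrix", "GeneDistanceSet", function(object, locus) {
  if (!locus %in% names(object@k)) stop("unknown locus: ", locus)
  object@k[[locus]]
})

#' @rdname accessors
#' @export
setGeneric("varianceMatrix",
           function(object, locus) standardGeneric("varianceMatrix"))
#' @rdname accessors
#' @export
setMethod("varianceMatrix", "GeneDistanceSet", function(object, locus) {
  if (!locus %in% names(object@V)) stop("unknown locus: ", locus)
  object@V[[locus]]
})

#' @rdname accessors
#' @export
setGeneric("weightMethod", function(object) standardGeneric("weightMethod"))
#' @rdname accessors
#' @export
setMethod("weightMethod", "WeightScheme", function(object) object@method)
#' @rdname accessors
#' @export
setMethod("weightMethod", "PooledDistance",
          function(object) object@scheme@method)

#' @rdname accessors
#' @export
setMethod("weights", "WeightScheme", function(object, ...) object@weights)

#' @rdname accessors
#' @export
setGeneric("pooledMatrix", function(object) standardGeneric("pooledMatrix"))
#' @rdname accessors
#' @export
setMethod("pooledMatrix", "PooledDistance", function(object) object@D)

setMethod("show", "LocusAlignment", function(object) {
  cat(sprintf("LocusAlignment '%s' (%s): %d taxa x %d sites\n",
              object@name, object@alphabet, nrow(object@seqs),
              ncol(object@seqs)))
})

setMethod("show", "MultiLocusDataset", function(object) {
  L <- locusLengths(object)
  cat(sprintf("MultiLocusDataset: %d loci, %d taxa\n",
              length(object@loci), length(object@taxa)))
  cat("  taxa:", paste(head(object@taxa, 6), collapse = ", "),
      if (length(object@taxa) > 6) "..." else "", "\n")
  cat(sprintf("  locus lengths: %d-%d sites (total %d)\n",
              min(L), max(L), sum(L)))
})

setMethod("show", "GeneDistanceSet", function(object) {
  cat(sprintf(
    "GeneDistanceSet (%s): %d loci, %d taxa%s\n", object@model,
    length(object@k), length(object@taxa),
    if (isTRUE(object@saturated)) " [saturation-clamped]" else ""))
})

setMethod("show", "WeightScheme", function(object) {
  cat(sprintf("WeightScheme '%s' (%s)\n", object@method, object@granularity))
  if (object@granularity == "per_gene") print(round(object@weights, 4))
  else cat(sprintf("  %d loci x %d pairs\n", nrow(object@weights),
                   ncol(object@weights)))
})

setMethod("show", "PooledDistance", function(object) {
  cat(sprintf("PooledDistance (%s) over %d taxa\n",
              object@scheme@method, nrow(object@D)))
  print(round(object@D, 4))
})
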