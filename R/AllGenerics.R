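#' @include AllClasses.R
NULL

#' Accessors for PhageCompare objects
#'
#' `genomeId()` returns the genome identifier; `genomeSeq()` the
#' [Biostrings::DNAString]; `topology()` the `"linear"`/`"circular"` flag;
#' `features()` the feature [GenomicRanges::GRanges]; `proteins()` the named
#' [Biostrings::AAStringSet] of a [Proteome]; `orthologPairs()` the pair table
#' of an [OrthologTable]; `partitionCounts()` the conserved/shared/unique
#' counts of a [TriadPartition].
#'
#' @param x An object of the relevant class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))
#' @rdname accessors
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))
#' @rdname accessors
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))
#' @rdname accessors
#' @export
setGeneric("features", function(x) standardGeneric("features"))
#' @rdname accessors
#' @export
setGeneric("proteins", function(x) standardGeneric("proteins"))
#' @rdname accessors
#' @export
setGeneric("orthologPairs", function(x) standardGeneric("orthologPairs"))
#' @rdname accessors
#' @export
setGeneric("partitionCounts", function(x) standardGeneric("partitionCounts"))

#' @rdname accessors
#' @export
setMethod("genomeId", "PhageGenome", function(x) x@id)
#' @rdname accessors
#' @export
setMethod("genomeId", "Proteome", function(x) x@genome_id)
#' @rdname accessors
#' @export
setMethod("genomeSeq", "PhageGenome", function(x) x@sequence)
#' @rdname accessors
#' @export
setMethod("topology", "PhageGenome", function(x) x@topology)
#' @rdname accessors
#' @export
setMethod("features", "PhageGenome", function(x) x@features)
#' @rdname accessors
#' @export
setMethod("proteins", "Proteome", function(x) x@proteins)
#' @rdname accessors
#' @export
setMethod("orthologPairs", "OrthologTable", function(x) x@pairs)

#' @rdname accessors
#' @export
setMethod("partitionCounts", "TriadPartition", function(x) {
  list(
    conserved_all = nrow(x@conserved),
    shared_two = vapply(x@genomes, function(g) length(x@shared_two[[g]]),
                        integer(1)),
    unique = vapply(x@genomes, function(g) length(x@unique_loci[[g]]),
                    integer(1)),
    n_genes = x@n_genes
  )
})

#' @rdname accessors
#' @param object An object of the relevant class.
#' @export
setMethod("length", "Proteome", function(x) length(x@proteins))

setMethod("show", "PhageGenome", function(object) {
  cat(sprintf("PhageGenome '%s' (%s): %s bp, %d feature(s)\n",
              object@id, object@topology,
              format(length(object@sequence), big.mark = ","),
              length(object@features)))
  if (nzchar(object@description))
    cat("  ", object@description, "\n", sep = "")
})

setMethod("show", "Proteome", function(object) {
  cat(sprintf("Proteome of '%s': %d protein(s), mean length %.0f aa\n",
              object@genome_id, length(object@proteins),
              if (length(object@proteins))
                mean(Biostrings::width(object@proteins)) else 0))
})

setMethod("show", "OrthologTable", function(object) {
  cat(sprintf(
    "OrthologTable %s vs %s: %d reciprocal pair(s) (identity >= %s%%, coverage >= %s%%)\n",
    object@genome_a, object@genome_b, nrow(object@pairs),
    object@params$min_identity, object@params$min_coverage))
})

setMethod("show", "TriadPartition", function(object) {
  cnt <- partitionCounts(object)
  cat(sprintf("TriadPartition of %s:\n", paste(object@genomes, collapse = ", ")))
  cat(sprintf("  conserved in all three: %d\n", cnt$conserved_all))
  cat(sprintf("  unique: %s\n",
              paste(sprintf("%s=%d", names(cnt$unique), cnt$unique),
                    collapse = ", ")))
})
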