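#' @import methods
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom GenomicRanges GRanges start end strand
#' @importFrom IRanges IRanges
#' @importFrom Biostrings DNAString DNAStringSet AAString AAStringSet
#' @importClassesFrom Biostrings DNAString DNAStringSet AAString AAStringSet
#' @importClassesFrom GenomicRanges GRanges
NULL

#' PhageGenome: a phage genome with its annotated features
#'
#' Container for a single phage genome sequence together with its topology
#' (linear or circular) and an ordered table of gene features. Feature
#' coordinates are 1-based inclusive on the forward strand, the convention
#' used throughout the package.
#'
#' @slot id Accession-like identifier.
#' @slot description Free-text description.
#' @slot sequence A [Biostrings::DNAString] over the A/C/G/T/N alphabet.
#' @slot topology Either `"linear"` or `"circular"`.
#' @slot features A [GenomicRanges::GRanges] with metadata columns
#'   `locus_id`, `kind` (one of `CDS`, `tRNA`, `other`) and `translation`
#'   (`NA` when absent).
#'
#' @seealso [readGenome()], [genomeStats()], [callOrfs()]
#' @export
setClass("PhageGenome",
  slots = c(
    id = "character",
    description = "character",
    sequence = "DNAString",
    topology = "character",
    features = "GRanges"
  )
)

setValidity("PhageGenome", function(object) {
  msg <- character()
  if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
    msg <- c(msg, "'id' must be a single non-empty string")
  if (!object@topology %in% c("linear", "circular"))
    msg <- c(msg, "'topology' must be 'linear' or 'circular'")
  if (length(object@sequence) == 0L)
    msg <- c(msg, "'sequence' must be non-empty")
  bad <- setdiff(unique(strsplit(as.character(object@sequence), "")[[1]]),
                 c("A", "C", "G", "T", "N"))
  if (length(bad))
    msg <- c(msg, paste0("sequence contains characters outside A/C/G/T/N: ",
                         paste(bad, collapse = ",")))
  ft <- object@features
  if (length(ft)) {
    need <- c("locus_id", "kind")
    if (!all(need %in% names(mcols(ft))))
      msg <- c(msg, "features must carry 'locus_id' and 'kind' metadata columns")
    if (any(GenomicRanges::start(ft) < 1L) ||
        any(GenomicRanges::end(ft) > length(object@sequence)))
      msg <- c(msg, "feature coordinates must lie within [1, genome length]")
    if (!all(as.character(GenomicRanges::strand(ft)) %in% c("+", "-")))
      msg <- c(msg, "feature strand must be '+' or '-'")
    if ("kind" %in% names(mcols(ft)) &&
        !all(mcols(ft)$kind %in% c("CDS", "tRNA", "other")))
      msg <- c(msg, "feature kind must be one of CDS/tRNA/other")
  }
  if (length(msg)) msg else TRUE
})

#' Proteome: the ordered protein complement of one genome
#'
#' Proteins are stored in gene order along the genome (needed by
#' [syntenyBlocks()]); locus identifiers are the names of the
#' [Biostrings::AAStringSet].
#'
#' @slot genome_id Identifier of the source genome.
#' @slot proteins Named [Biostrings::AAStringSet], order = gene order.
#' @export
setClass("Proteome",
  slots = c(genome_id = "character", proteins = "AAStringSet")
)

setValidity("Proteome", function(object) {
  msg <- character()
  if (length(object@genome_id) != 1L || !nzchar(object@genome_id))
    msg <- c(msg, "'genome_id' must be a single non-empty string")
  nm <- names(object@proteins)
  if (length(object@proteins)) {
    if (is.null(nm) || any(!nzchar(nm)))
      msg <- c(msg, "all proteins must be named by locus id")
    if (anyDuplicated(nm))
      msg <- c(msg, "locus ids must be unique")
    if (any(Biostrings::width(object@proteins) == 0L))
      msg <- c(msg, "proteins must be non-empty")
    letters_used <- unique(strsplit(
      paste(as.character(object@proteins), collapse = ""), "")[[1]])
    if (length(setdiff(letters_used, c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X"))))
      msg <- c(msg, "proteins must use the 20-letter alphabet plus X")
  }
  if (length(msg)) msg else TRUE
})

#' OrthologTable: reciprocal-best-hit pairs between two proteomes
#'
#' One row per ortholog pair after reciprocal-best-hit filtering at the
#' identity/coverage thresholds; each locus appears in at most one pair.
#' Alignment statistics are stored for both directions (scores are symmetric
#' under the substitution matrix; coverages can differ under the `query`
#' coverage mode).
#'
#' @slot genome_a,genome_b Identifiers of the two proteomes.
#' @slot pairs data.frame with columns `locus_a`, `locus_b`, `score`,
#'   `identity_ab`, `coverage_ab`, `identity_ba`, `coverage_ba`.
#' @slot params List of the thresholds used.
#' @export
setClass("OrthologTable",
  slots = c(
    genome_a = "character",
    genome_b = "character",
    pairs = "data.frame",
    params = "list"
  )
)

setValidity("OrthologTable", function(object) {
  msg <- character()
  need <- c("locus_a", "locus_b", "score",
            "identity_ab", "coverage_ab", "identity_ba", "coverage_ba")
  if (!all(need %in% names(object@pairs)))
    msg <- c(msg, paste0("pairs must have columns: ", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(object@pairs$locus_a) || anyDuplicated(object@pairs$locus_b))
      msg <- c(msg, "each locus may appear in at most one pair")
    idc <- unlist(object@pairs[c("identity_ab", "identity_ba")])
    cvc <- unlist(object@pairs[c("coverage_ab", "coverage_ba")])
    if (length(idc) && (any(idc < 0) || any(idc > 100)))
      msg <- c(msg, "identities must lie in [0,100]")
    if (length(cvc) && (any(cvc < 0) || any(cvc > 100 + 1e-9)))
      msg <- c(msg, "coverages must lie in [0,100]")
  }
  if (length(msg)) msg else TRUE
})

#' TriadPartition: conserved/unique partition across three proteomes
#'
#' @slot genomes The three genome identifiers.
#' @slot n_genes Named integer vector, proteome sizes.
#' @slot conserved data.frame of three-way ortholog triples
#'   (columns named by genome).
#' @slot shared_two Named list (per genome) of loci in at least one pairwise
#'   ortholog relation but not in a three-way triple.
#' @slot unique_loci Named list (per genome) of loci with no qualifying
#'   ortholog in either other genome.
#' @slot tables List of the three pairwise [OrthologTable]s (`ab`,`ac`,`bc`).
#' @export
setClass("TriadPartition",
  slots = c(
    genomes = "character",
    n_genes = "integer",
    conserved = "data.frame",
    shared_two = "list",
    unique_loci = "list",
    tables = "list"
  )
)

setValidity("TriadPartition", function(object) {
  msg <- character()
  if (length(object@genomes) != 3L)
    msg <- c(msg, "exactly three genomes required")
  for (g in object@genomes) {
    tot <- nrow(object@conserved) +
      length(object@shared_two[[g]]) + length(object@unique_loci[[g]])
    if (!is.na(object@n_genes[g]) && tot != object@n_genes[g])
      msg <- c(msg, sprintf(
        "partition of genome %s does not cover the proteome (%d vs %d loci)",
        g, tot, object@n_genes[g]))
  }
  if (length(msg)) msg else TRUE
})
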