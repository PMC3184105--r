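#' Read a phage genome from FASTA or GenBank
#'
#' Sequences are upper-cased on input; ambiguity codes other than `N` are
#' rejected because the downstream scanners assume a 4-letter alphabet.
#' GenBank CDS/tRNA features are imported with their locus tags and
#' translations; CDS features without a `/translation` qualifier are
#' translated with the bacterial genetic code (table 11).
#'
#' @param path Path to the file.
#' @param format `"auto"` (default, decided from the first line), `"fasta"`
#'   or `"genbank"`.
#' @param topology Topology to assign to FASTA records (`"linear"` default);
#'   GenBank records carry their own topology flag on the LOCUS line.
#' @param multi What to do with a multi-record FASTA: `"error"` (default) or
#'   `"first"` (keep the first record with a warning).
#' @return A [PhageGenome].
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">x test", "ATGC"), fa)
#' g <- readGenome(fa)
#' genomeStats(g)$gc_percent  # 50.0
#' @export
readGenome <- function(path, format = c("auto", "fasta", "genbank"),
                       topology = "linear", multi = c("error", "first")) {
  format <- match.arg(format)
  multi <- match.arg(multi)
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (length(first) && startsWith(first, "LOCUS")) "genbank"
              else "fasta"
  }
  if (format == "genbank") return(.readGenBank(path))

  recs <- tryCatch(Biostrings::readDNAStringSet(path),
                   error = function(e) stop(sprintf(
                     "FASTA format error in '%s': %s", path,
                     conditionMessage(e)), call. = FALSE))
  if (length(recs) == 0L)
    stop(sprintf("empty-input error: '%s' contains no records", path))
  if (length(recs) > 1L) {
    if (multi == "error")
      stop(sprintf("'%s' contains %d records; pass multi='first' to keep the first",
                   path, length(recs)))
    warning(sprintf("'%s' contains %d records; keeping the first", path,
                    length(recs)))
    recs <- recs[1]
  }
  header <- names(recs)[[1]]
  id <- strsplit(header, "[[:space:]]+")[[1]][[1]]
  desc <- sub(paste0("^", id, "[[:space:]]*"), "", header)
  seq_chr <- toupper(as.character(recs[[1]]))
  if (!nzchar(seq_chr))
    stop(sprintf("empty-input error: record '%s' has an empty sequence", id))
  .checkAlphabet(seq_chr, where = sprintf("record '%s'", id))
  new("PhageGenome", id = id, description = desc,
      sequence = Biostrings::DNAString(seq_chr),
      topology = topology,
      features = GenomicRanges::GRanges())
}

#' Basic genome statistics
#'
#' GC percent is `100 * (G + C) / (A + C + G + T)`; `N` bases are excluded
#' from the denominator. Reported to one decimal.
#'
#' @param g A [PhageGenome].
#' @return A list with `length_bp`, `gc_percent` and `n_features_by_kind`.
#' @export
genomeStats <- function(g) {
  stopifnot(is(g, "PhageGenome"))
  cnt <- Biostrings::alphabetFrequency(g@sequence)[c("A", "C", "G", "T", "N")]
  acgt <- sum(cnt[c("A", "C", "G", "T")])
  if (acgt == 0L)
    stop("undefined-GC error: sequence contains no A/C/G/T bases")
  kinds <- mcols(g@features)$kind
  out <- list(
    length_bp = length(g@sequence),
    gc_percent = round(100 * sum(cnt[c("G", "C")]) / acgt, 1),
    n_features_by_kind = if (length(kinds)) table(kinds) else
      table(factor(character(), levels = c("CDS", "tRNA", "other")))
  )
  class(out) <- "genome_stats"
  out
}

#' @export
print.genome_stats <- function(x, ...) {
  cat(sprintf("Genome: %s bp, GC %.1f%%\n",
              format(x$length_bp, big.mark = ","), x$gc_percent))
  if (sum(x$n_features_by_kind))
    print(x$n_features_by_kind)
  invisible(x)
}

#' Write sequences as 60-column wrapped FASTA
#'
#' @param records A [PhageGenome], [Proteome], [Biostrings::XStringSet], or a
#'   named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly. Round-trips through [readGenome()] /
#'   [readProteome()].
#' @export
writeFasta <- function(records, path) {
  if (is(records, "PhageGenome")) {
    x <- Biostrings::DNAStringSet(as.character(records@sequence))
    names(x) <- paste(records@id, records@description)
    names(x) <- trimws(names(x))
  } else if (is(records, "Proteome")) {
    x <- records@proteins
  } else if (is(records, "XStringSet")) {
    x <- records
  } else if (is.character(records)) {
    if (is.null(names(records)) || any(!nzchar(names(records))))
      stop("character records must be named")
    x <- Biostrings::BStringSet(records)
  } else stop("unsupported records type")
  if (length(x) == 0L) {
    warning("writing an empty FASTA file")
    file.create(path)
    return(invisible(path))
  }
  ids <- sub("[[:space:]].*$", "", names(x))
  if (is.null(names(x)) || any(!nzchar(ids)))
    stop("all records must have ids")
  if (anyDuplicated(ids))
    stop(sprintf("duplicate record ids: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ",")))
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read a protein FASTA as a Proteome
#'
#' Record order in the file is taken as gene order on the genome.
#'
#' @param path Protein FASTA path.
#' @param genome_id Identifier of the source genome (default: file base name).
#' @return A [Proteome].
#' @export
readProteome <- function(path, genome_id = NULL) {
  aa <- Biostrings::readAAStringSet(path)
  if (!length(aa)) stop(sprintf("empty-input error: '%s' has no records", path))
  names(aa) <- sub("[[:space:]].*$", "", names(aa))
  # trailing stops are an artifact of whole-CDS translation
  aa <- Biostrings::AAStringSet(sub("\\*$", "", as.character(aa)))
  if (is.null(genome_id))
    genome_id <- sub("\\.[^.]*$", "", basename(path))
  new("Proteome", genome_id = genome_id, proteins = aa)
}

#' Extract the proteome of an annotated genome
#'
#' Uses stored CDS translations (computing any that are missing with genetic
#' code table 11), in gene order along the genome.
#'
#' @param g A [PhageGenome] with CDS features.
#' @return A [Proteome].
#' @export
proteomeFromGenome <- function(g) {
  stopifnot(is(g, "PhageGenome"))
  idx <- which(mcols(g@features)$kind == "CDS")
  if (!length(idx)) stop(sprintf("genome '%s' has no CDS features", g@id))
  idx <- idx[order(GenomicRanges::start(g@features)[idx])]
  tr <- mcols(g@features)$translation[idx]
  for (j in which(is.na(tr))) tr[j] <- translateCds(g, featureAt(g, idx[j]))
  aa <- Biostrings::AAStringSet(tr)
  names(aa) <- mcols(g@features)$locus_id[idx]
  new("Proteome", genome_id = g@id, proteins = aa)
}

#' Single feature accessor
#'
#' @param g A [PhageGenome].
#' @param i Feature index.
#' @return A length-one [GenomicRanges::GRanges] for that feature.
#' @export
featureAt <- function(g, i) g@features[i]
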